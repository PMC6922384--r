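KS_CONST <- 0.084 * 332  # electrostatic H-bond energy prefactor, kcal/mol·Å

#' Backbone hydrogen-bond detection (Kabsch–Sander energy)
#'
#' Detects main-chain hydrogen bonds with the electrostatic model used for
#' secondary-structure assignment:
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol for each
#' donor (N-H of residue i) / acceptor (C=O of residue j) candidate. Amide
#' hydrogens are always reconstructed geometrically (unit bisector of
#' C(i-1)→N and CA→N directions, N–H 1.0 Å); hydrogens present in the file
#' are ignored for consistency. Proline has no amide hydrogen and is never a
#' donor. Candidates are limited to N–O distances below `no_cutoff` and
#' sequence separation |i - j| >= 2; at most two acceptors per donor are
#' kept (best energies).
#'
#' @param domain A `domain_structure`.
#' @param energy_cutoff Bonds with energy below this value (kcal/mol) are
#'   reported; default -0.5.
#' @param no_cutoff N–O candidate prefilter distance (Å).
#' @return Data frame with columns `donor`, `acceptor` (local indices),
#'   `energy` (kcal/mol). Residues with incomplete backbones are skipped
#'   with a warning.
#' @export
detect_hbonds <- function(domain, energy_cutoff = -0.5, no_cutoff = 5.2) {
  bb <- backbone_arrays(domain)
  if (length(bb$skipped)) {
    warning("skipping residues with incomplete backbone: ",
            paste(bb$skipped, collapse = ", "))
  }
  hb <- ks_hbonds(bb, energy_cutoff, no_cutoff)
  hb[order(hb$donor, hb$acceptor), , drop = FALSE]
}

## Gather N/CA/C/O coordinate arrays indexed by local residue index and
## reconstruct amide H positions.
backbone_arrays <- function(domain) {
  a <- domain$atoms
  idx <- sort(unique(a$local_index))
  get <- function(name) {
    sel <- a[a$elety == name, , drop = FALSE]
    m <- matrix(NA_real_, length(idx), 3)
    m[match(sel$local_index, idx), ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  N <- get("N"); CA <- get("CA"); C <- get("C"); O <- get("O")
  complete <- rowSums(is.na(cbind(N, CA, C, O))) == 0
  res3 <- residue_table(domain)$resid
  ## reconstructed amide H: N + 1.0 * unit(unit(N - C_prev) + unit(N - CA))
  H <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)[-1]) {
    if (!complete[k] || !complete[k - 1]) next
    if (res3[k] == "PRO") next
    u1 <- N[k, ] - C[k - 1, ]
    u2 <- N[k, ] - CA[k, ]
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- u2 / sqrt(sum(u2^2))
    b <- u1 + u2
    H[k, ] <- N[k, ] + b / sqrt(sum(b^2))
  }
  list(idx = idx, N = N, CA = CA, C = C, O = O, H = H,
       complete = complete, skipped = idx[!complete])
}

ks_energy <- function(rON, rCH, rOH, rCN) {
  e <- KS_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  pmax(e, -9.9)  # clamp near-clash geometries as in standard practice
}

ks_hbonds <- function(bb, energy_cutoff, no_cutoff) {
  n <- length(bb$idx)
  res <- list()
  for (k in seq_len(n)) {
    if (any(is.na(bb$H[k, ]))) next  # no donor H (Pro, chain start, gap)
    dNO <- sqrt(colSums((t(bb$O) - bb$N[k, ])^2))
    cand <- which(bb$complete & abs(seq_len(n) - k) >= 2 & dNO < no_cutoff)
    if (!length(cand)) next
    rON <- dNO[cand]
    rCH <- sqrt(rowSums((bb$C[cand, , drop = FALSE] -
                           matrix(bb$H[k, ], length(cand), 3, byrow = TRUE))^2))
    rOH <- sqrt(rowSums((bb$O[cand, , drop = FALSE] -
                           matrix(bb$H[k, ], length(cand), 3, byrow = TRUE))^2))
    rCN <- sqrt(rowSums((bb$C[cand, , drop = FALSE] -
                           matrix(bb$N[k, ], length(cand), 3, byrow = TRUE))^2))
    e <- ks_energy(rON, rCH, rOH, rCN)
    keep <- e < energy_cutoff
    if (!any(keep)) next
    ord <- order(e[keep])[seq_len(min(2, sum(keep)))]  # best two acceptors
    res[[length(res) + 1]] <- data.frame(
      donor = bb$idx[k],
      acceptor = bb$idx[cand[keep][ord]],
      energy = e[keep][ord]
    )
  }
  if (!length(res)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric()))
  }
  do.call(rbind, res)
}

#' Assign β-sheet topology and strand labels
#'
#' Finds β-bridges from the hydrogen-bond list using the standard
#' antiparallel (`(i,j)` and `(j,i)` bonds, or `(i-1,j+1)` and `(j-1,i+1)`)
#' and parallel (`(i-1,j)`/`(j,i+1)` or `(j-1,i)`/`(i,j+1)`) patterns,
#' merges bridge runs into strands (>= `min_strand` residues), partitions
#' strands into sheets by ladder connectivity, and detects 3₁₀ helices as
#' runs of at least two consecutive i+3 → i hydrogen bonds. When nine
#' strands in two sheets are found, the canonical Ig labels
#' A, A', B, C, C', D, E, F, G are assigned in sequence order and the two
#' sheets are named after their strands (ABDE and A'CC'FG); otherwise labels
#' are assigned best effort with a warning.
#'
#' @param domain A `domain_structure`.
#' @param hbonds Bond table from [detect_hbonds()]; computed if missing.
#' @param min_strand Minimum strand length in residues.
#' @return A `sheet_assignment`: data frame `residues` (local_index, state
#'   in strand/3-10/loop, strand_label, sheet, loop_name, tip), data frame
#'   `strands` (label, from, to, sheet), `sheets` (named residue-index
#'   lists), and `bridges` (i, j, type).
#' @export
assign_topology <- function(domain, hbonds = NULL, min_strand = 3) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(domain)
  idx <- sort(unique(domain$atoms$local_index))
  n <- length(idx)
  pos <- function(i) match(i, idx)
  B <- matrix(FALSE, n, n)
  if (nrow(hbonds)) B[cbind(pos(hbonds$donor), pos(hbonds$acceptor))] <- TRUE
  hb <- function(i, j) {
    i >= 1 && j >= 1 && i <= n && j <= n && B[i, j]
  }
  ## bridge detection over all residue pairs with |i-j| > 2
  bridges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 2) next
      anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      para <- (hb(i - 1, j) && hb(j, i + 1)) || (hb(j - 1, i) && hb(i, j + 1))
      if (anti || para) {
        bridges[[length(bridges) + 1]] <-
          data.frame(i = i, j = j, type = if (anti) "antiparallel" else "parallel")
      }
    }
  }
  bridges <- if (length(bridges)) do.call(rbind, bridges) else
    data.frame(i = integer(), j = integer(), type = character())
  in_bridge <- sort(unique(c(bridges$i, bridges$j)))
  ## strands: maximal consecutive runs of bridge-forming residues
  strands <- consecutive_runs(in_bridge, min_len = min_strand)
  ## sheet partition: strands connected by any bridge share a sheet
  ns <- nrow(strands)
  strand_of <- rep(NA_integer_, n)
  for (s in seq_len(ns)) strand_of[strands$from[s]:strands$to[s]] <- s
  comp <- seq_len(ns)
  if (nrow(bridges)) {
    for (b in seq_len(nrow(bridges))) {
      si <- strand_of[bridges$i[b]]
      sj <- strand_of[bridges$j[b]]
      if (is.na(si) || is.na(sj) || si == sj) next
      old <- comp[sj]
      comp[comp == old] <- comp[si]
    }
  }
  sheet_id <- match(comp, unique(comp))
  ## 3-10 helix: >= 2 consecutive i+3 -> i bonds
  turn3 <- logical(n)
  if (nrow(hbonds)) {
    t3 <- sort(unique(pos(hbonds$acceptor[hbonds$donor - hbonds$acceptor == 3])))
    for (s in t3) {
      if ((s + 1) %in% t3) turn3[s:(min(s + 4, n))] <- TRUE
    }
  }
  ## labels
  if (ns == 9 && length(unique(sheet_id)) == 2) {
    labels <- c("A", "A'", "B", "C", "C'", "D", "E", "F", "G")
  } else {
    if (ns < 7) {
      warning("found ", ns, " strands (expected 9 for an Ig fold); ",
              "labels assigned best-effort")
    }
    labels <- LETTERS[seq_len(max(ns, 0))]
  }
  strands$label <- labels[seq_len(ns)]
  strands$sheet <- sheet_id
  sheet_names <- vapply(sort(unique(sheet_id)), function(sid) {
    paste(strands$label[strands$sheet == sid], collapse = "")
  }, character(1))
  strands$sheet_name <- sheet_names[strands$sheet]
  state <- rep("loop", n)
  state[!is.na(strand_of)] <- "strand"
  state[turn3 & state == "loop"] <- "3-10"
  strand_label <- ifelse(is.na(strand_of), NA_character_, strands$label[strand_of])
  sheet_name <- ifelse(is.na(strand_of), NA_character_, strands$sheet_name[strand_of])
  ## loops named by flanking strands; tip assignment per the Ig convention
  loop_name <- rep(NA_character_, n)
  if (ns >= 2) {
    for (s in seq_len(ns - 1)) {
      from <- strands$to[s] + 1
      to <- strands$from[s + 1] - 1
      if (from <= to) {
        loop_name[from:to] <- paste0(strands$label[s], strands$label[s + 1])
      }
    }
  }
  n_tip <- c("BC", "DE", "FG")
  c_tip <- c("A'B", "C'D", "EF")
  tip <- ifelse(loop_name %in% n_tip, "N-tip",
                ifelse(loop_name %in% c_tip, "C-tip", NA_character_))
  residues <- data.frame(
    local_index = idx, state = state, strand_label = strand_label,
    sheet = sheet_name, loop_name = loop_name, tip = tip,
    stringsAsFactors = FALSE
  )
  bridges$i <- idx[bridges$i]
  bridges$j <- idx[bridges$j]
  strands$from <- idx[strands$from]
  strands$to <- idx[strands$to]
  out <- list(residues = residues,
              strands = strands[, c("label", "from", "to", "sheet", "sheet_name")],
              bridges = bridges,
              has_310 = any(turn3))
  class(out) <- "sheet_assignment"
  out
}

#' @export
print.sheet_assignment <- function(x, ...) {
  cat("sheet_assignment:", nrow(x$strands), "strands in",
      length(unique(x$strands$sheet)), "sheet(s);",
      if (x$has_310) "3-10 helix present" else "no 3-10 helix", "\n")
  invisible(x)
}

consecutive_runs <- function(v, min_len = 1) {
  if (!length(v)) return(data.frame(from = integer(), to = integer()))
  breaks <- c(0, which(diff(v) > 1), length(v))
  runs <- data.frame(
    from = v[breaks[-length(breaks)] + 1],
    to = v[breaks[-1]]
  )
  runs[runs$to - runs$from + 1 >= min_len, , drop = FALSE]
}

#' Cross-structure hydrogen-bond conservation
#'
#' Maps every backbone hydrogen bond of every domain into master-alignment
#' column space: a bond is structurally identical across structures when
#' both its donor and acceptor residues map to the same columns. Bonds are
#' attributed to the β-sheet of their participating strands in the owning
#' structure, with a separate C-tip category for bonds touching the A'B,
#' C'D or EF loops.
#'
#' @param domains Named list of `domain_structure` objects.
#' @param master A `master_alignment` over the same domains
#'   (see [build_master_alignment()]).
#' @param hbond_args Arguments passed on to [detect_hbonds()].
#' @return A list with `table` (data frame: donor/acceptor column, count,
#'   class, sheet category) and `per_sheet` (named conserved-bond counts at
#'   class >= (n-1)/n).
#' @export
hbond_conservation <- function(domains, master, hbond_args = list()) {
  nS <- length(domains)
  labs <- names(domains)
  rows <- list()
  for (lab in labs) {
    d <- domains[[lab]]
    hb <- do.call(detect_hbonds, c(list(d), hbond_args))
    topo <- assign_topology(d, hb)
    col_of <- master_column_lookup(master, lab)
    rr <- topo$residues
    for (b in seq_len(nrow(hb))) {
      cd <- col_of[as.character(hb$donor[b])]
      ca <- col_of[as.character(hb$acceptor[b])]
      if (is.na(cd) || is.na(ca)) next
      sd_ <- rr$sheet[rr$local_index == hb$donor[b]]
      sa <- rr$sheet[rr$local_index == hb$acceptor[b]]
      sheet <- if (!is.na(sd_)) sd_ else sa
      tips <- c(rr$tip[rr$local_index == hb$donor[b]],
                rr$tip[rr$local_index == hb$acceptor[b]])
      ctip <- any(!is.na(tips) & tips == "C-tip")
      rows[[length(rows) + 1]] <- data.frame(
        structure = lab, col_donor = cd, col_acceptor = ca,
        sheet = if (is.na(sheet)) NA_character_ else sheet,
        c_tip = ctip, stringsAsFactors = FALSE
      )
    }
  }
  all <- do.call(rbind, rows)
  key <- paste(all$col_donor, all$col_acceptor)
  counts <- table(key)[paste(all$col_donor, all$col_acceptor)]
  all$count <- as.integer(counts)
  uniq <- all[!duplicated(key), , drop = FALSE]
  uniq$class <- ifelse(uniq$count >= nS, sprintf("%d/%d", nS, nS),
                       ifelse(uniq$count < 3, "<3",
                              sprintf("%d/%d", uniq$count, nS)))
  conserved <- uniq[uniq$count >= nS - 1, , drop = FALSE]
  sheets <- sort(unique(conserved$sheet[!is.na(conserved$sheet)]))
  per_sheet <- vapply(sheets, function(s) {
    sum(conserved$sheet == s & !conserved$c_tip, na.rm = TRUE)
  }, numeric(1))
  per_sheet <- c(per_sheet, `C-tip` = sum(conserved$c_tip))
  list(table = uniq[order(-uniq$count), ], per_sheet = per_sheet)
}
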