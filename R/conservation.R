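## physicochemical substitution classes used for the "conserved" category
CONSERVED_GROUPS_DEFAULT <- list(c("I", "L", "V", "M"), c("F", "Y", "W"),
                                 c("K", "R"), c("D", "E"), c("S", "T"),
                                 c("N", "Q"))

#' Global pairwise sequence alignment (Needleman–Wunsch, affine gaps)
#'
#' Optimal global alignment with BLOSUM62 scoring and affine gap costs
#' (a gap of length L costs `gap_open + L * gap_extend`). The alignment is
#' delegated to the standard dynamic-programming implementation in
#' Biostrings; identity is the fraction of identical residues over aligned
#' (non-gap) column pairs.
#'
#' @param a,b Amino-acid strings.
#' @param matrix Substitution matrix name, default `"BLOSUM62"`.
#' @param gap_open,gap_extend Affine gap parameters (11, 1).
#' @return List: `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `identity` (%).
#' @export
needleman_wunsch <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend
  )
  sa <- as.character(Biostrings::alignedPattern(al))
  sb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  paired <- ca != "-" & cb != "-"
  list(aligned_a = sa, aligned_b = sb,
       score = Biostrings::score(al),
       identity = 100 * sum(ca == cb & paired) / sum(paired))
}

#' Reference-anchored structure-based multiple alignment
#'
#' Builds a master alignment of several Ig domains anchored on the residues
#' of a reference domain: every other domain is aligned to the reference
#' with [structure_align()], and its residues are placed in the column of
#' their reference partner. Pairs outside the superposition core are kept
#' but flagged uncertain (rendered lower case). Residues with no reference
#' partner become insertion columns after their last anchored neighbour.
#'
#' @param domains Named list of `domain_structure` objects.
#' @param reference Label of the reference domain (must be in `domains`).
#' @param ... Arguments passed to [structure_align()].
#' @return A `master_alignment`: data frame `columns` with one row per
#'   column (`column`, `ref_index`) plus, per domain, `<label>_idx`,
#'   `<label>_aa`, `<label>_certain`.
#' @export
build_master_alignment <- function(domains, reference = names(domains)[1],
                                   ...) {
  stopifnot(reference %in% names(domains))
  ref <- domains[[reference]]
  rt <- residue_table(ref)
  rt <- rt[!rt$tag, ]
  labs <- names(domains)
  ncol0 <- nrow(rt)
  cols <- data.frame(column = seq_len(ncol0), ref_index = rt$local_index)
  per <- list()
  per[[reference]] <- data.frame(
    idx = rt$local_index, aa = rt$aa, certain = TRUE, col = seq_len(ncol0))
  ins_after <- list()  # insertions keyed by preceding column
  for (lab in setdiff(labs, reference)) {
    d <- domains[[lab]]
    if (identical(lab, reference)) next
    al <- structure_align(ref, d, ...)
    m <- match(al$pairs$i, rt$local_index)
    rtd <- residue_table(d)
    rtd <- rtd[!rtd$tag, ]
    placed <- data.frame(idx = al$pairs$j,
                         aa = rtd$aa[match(al$pairs$j, rtd$local_index)],
                         certain = al$pairs$core, col = m)
    ## unmatched runs -> insertion records after the previous anchored column
    un <- setdiff(rtd$local_index, al$pairs$j)
    for (u in un) {
      prev <- max(c(0, m[al$pairs$j < u]))
      ins_after[[as.character(prev)]] <- unique(c(
        ins_after[[as.character(prev)]], paste(lab, u)))
    }
    per[[lab]] <- placed
  }
  ## expand to column table, inserting extra columns where needed
  n_ins <- vapply(as.character(0:ncol0), function(k) {
    length(ins_after[[k]])
  }, integer(1))
  total <- ncol0 + sum(n_ins)
  out <- data.frame(column = seq_len(total),
                    ref_index = NA_integer_)
  for (lab in labs) {
    out[[paste0(lab, "_idx")]] <- NA_integer_
    out[[paste0(lab, "_aa")]] <- NA_character_
    out[[paste0(lab, "_certain")]] <- NA
  }
  colpos <- integer(ncol0)  # final position of anchored column c
  pos <- n_ins[1]
  for (cc in seq_len(ncol0)) {
    pos <- pos + 1
    colpos[cc] <- pos
    pos <- pos + n_ins[cc + 1]
  }
  out$ref_index[colpos] <- cols$ref_index
  for (lab in labs) {
    p <- per[[lab]]
    rows <- colpos[p$col]
    out[[paste0(lab, "_idx")]][rows] <- p$idx
    out[[paste0(lab, "_aa")]][rows] <- p$aa
    out[[paste0(lab, "_certain")]][rows] <- p$certain
  }
  ## fill insertion columns
  for (k in as.character(0:ncol0)) {
    entries <- ins_after[[k]]
    if (is.null(entries)) next
    base <- if (k == "0") 0 else colpos[as.integer(k)]
    slot <- base + 1
    for (e in entries) {
      sp <- strsplit(e, " ")[[1]]
      lab <- sp[1]; u <- as.integer(sp[2])
      rtd <- residue_table(domains[[lab]])
      while (slot <= total && !is.na(out[[paste0(lab, "_idx")]][slot])) {
        slot <- slot + 1
      }
      if (slot > total) break
      out[[paste0(lab, "_idx")]][slot] <- u
      out[[paste0(lab, "_aa")]][slot] <- rtd$aa[match(u, rtd$local_index)]
      out[[paste0(lab, "_certain")]][slot] <- FALSE
    }
  }
  res <- list(columns = out, reference = reference, labels = labs)
  class(res) <- "master_alignment"
  res
}

#' @export
print.master_alignment <- function(x, ...) {
  cat("master_alignment:", length(x$labels), "domains,",
      nrow(x$columns), "columns (reference", paste0(x$reference, ")"), "\n")
  invisible(x)
}

## named lookup local_index -> column for one domain
master_column_lookup <- function(master, label) {
  cols <- master$columns
  idx <- cols[[paste0(label, "_idx")]]
  ok <- !is.na(idx)
  mx <- max(idx, na.rm = TRUE)
  v <- rep(NA_integer_, mx)
  v[idx[ok]] <- cols$column[ok]
  setNames(v, seq_len(mx))
}

#' Aligned-FASTA rendering of a master alignment
#'
#' Uncertain positions are rendered in lower case, gaps as `-`.
#' @param master A `master_alignment`.
#' @return Named character vector of gapped sequences.
#' @export
master_alignment_fasta <- function(master) {
  cols <- master$columns
  out <- character(0)
  for (lab in master$labels) {
    aa <- cols[[paste0(lab, "_aa")]]
    cert <- cols[[paste0(lab, "_certain")]]
    aa[is.na(aa)] <- "-"
    low <- !is.na(cert) & !cert
    aa[low] <- tolower(aa[low])
    out[lab] <- paste(aa, collapse = "")
  }
  out
}

#' Assign query sequences to the human domain of highest identity
#'
#' @param queries Named character vector of query domain sequences.
#' @param human_domains Named character vector of human reference domain
#'   sequences.
#' @return Data frame: `query`, `domain`, `identity`; ties broken toward
#'   the first domain in input order (and reported in `tie`).
#' @export
assign_domains_by_identity <- function(queries, human_domains) {
  out <- lapply(names(queries), function(q) {
    ids <- vapply(human_domains, function(h) {
      needleman_wunsch(queries[[q]], h)$identity
    }, numeric(1))
    best <- which.max(ids)  # first maximum: deterministic tie-break
    data.frame(query = q, domain = names(human_domains)[best],
               identity = ids[best],
               tie = sum(ids == ids[best]) > 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify master-alignment columns into conservation categories
#'
#' Categories follow the comparative-fingerprint scheme: `invariant`
#' (identical residue in every domain at that column, and in every species
#' for each domain when a panel is supplied), `conserved` (all residues in
#' one physicochemical class), `domain_specific_signature` (at least two
#' distinct residues across domains, each domain invariant across its
#' species), otherwise `variable`. Columns missing in any domain are
#' `variable` by definition.
#'
#' @param master A `master_alignment`.
#' @param panel Optional species panel: named list domain -> named character
#'   vector of species sequences (first species = the sequence the domain
#'   structures use). Missing domains in a species are simply absent.
#' @param conserved_groups List of residue classes for the `conserved`
#'   category.
#' @return List: `categories` (per column), `counts`, and the augmented
#'   columns table.
#' @export
classify_columns <- function(master, panel = NULL,
                             conserved_groups = CONSERVED_GROUPS_DEFAULT) {
  cols <- master$columns
  labs <- master$labels
  n <- nrow(cols)
  ## per-domain species residues at each domain position
  species_res <- list()
  if (!is.null(panel)) {
    for (lab in intersect(labs, names(panel))) {
      sp <- panel[[lab]]
      refseq <- sp[[1]]
      mat <- matrix(NA_character_, nchar(refseq), length(sp))
      mat[, 1] <- strsplit(refseq, "")[[1]]
      for (k in seq_along(sp)[-1]) {
        al <- needleman_wunsch(refseq, sp[[k]])
        ca <- strsplit(al$aligned_a, "")[[1]]
        cb <- strsplit(al$aligned_b, "")[[1]]
        ri <- cumsum(ca != "-")
        keep <- ca != "-"
        mat[ri[keep], k] <- cb[keep]
      }
      species_res[[lab]] <- mat
    }
  }
  group_of <- function(aa) {
    for (g in seq_along(conserved_groups)) {
      if (aa %in% conserved_groups[[g]]) return(g)
    }
    -match(aa, AA_ALPHABET)  # singleton class
  }
  categories <- character(n)
  for (i in seq_len(n)) {
    res <- vapply(labs, function(lab) {
      v <- cols[[paste0(lab, "_aa")]][i]
      if (is.na(v)) NA_character_ else v
    }, character(1))
    if (any(is.na(res))) {
      categories[i] <- "variable"
      next
    }
    species_inv <- TRUE
    if (!is.null(panel)) {
      for (lab in names(species_res)) {
        pos <- cols[[paste0(lab, "_idx")]][i]
        if (is.na(pos) || pos > nrow(species_res[[lab]])) next
        row <- species_res[[lab]][pos, ]
        row <- row[!is.na(row)]
        if (length(unique(row)) > 1) {
          species_inv <- FALSE
          break
        }
      }
    }
    cross_identical <- length(unique(res)) == 1
    cross_conserved <- length(unique(vapply(res, group_of, numeric(1)))) == 1
    if (cross_identical && species_inv) {
      categories[i] <- "invariant"
    } else if (cross_conserved && species_inv) {
      categories[i] <- "conserved"
    } else if (!cross_identical && species_inv && !is.null(panel)) {
      categories[i] <- "domain_specific_signature"
    } else {
      categories[i] <- "variable"
    }
  }
  cols$category <- categories
  list(categories = categories,
       counts = table(factor(categories,
                             levels = c("invariant", "conserved",
                                        "domain_specific_signature",
                                        "variable"))),
       columns = cols)
}

#' Cross-species identity per domain with colour class
#'
#' @param panel Species panel as in [classify_columns()].
#' @return Data frame: `domain`, `species`, `identity`, `class`
#'   (`red` > 85%, `orange` > 70%, `yellow` > 50%, else `none`).
#' @export
cross_species_identity <- function(panel) {
  rows <- list()
  for (lab in names(panel)) {
    sp <- panel[[lab]]
    human <- sp[[1]]
    for (k in seq_along(sp)) {
      id <- if (k == 1) 100 else needleman_wunsch(human, sp[[k]])$identity
      rows[[length(rows) + 1]] <- data.frame(
        domain = lab, species = names(sp)[k], identity = id,
        class = if (id > 85) "red" else if (id > 70) "orange"
                else if (id > 50) "yellow" else "none",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), filepath = path)
  invisible(path)
}
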