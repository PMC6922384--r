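#' Optimal rigid-body superposition (Kabsch)
#'
#' Computes the least-squares rigid transform mapping `coords_A` onto
#' `coords_B` by singular value decomposition of the weighted covariance
#' matrix, with the reflection corrected so that a proper rotation
#' (det = +1) is always returned.
#'
#' @param coords_A,coords_B n x 3 coordinate matrices (Å), matched row-wise.
#' @param weights Optional non-negative weights, length n.
#' @return A `superposition` object with elements `rotation` (3x3, applied
#'   as `coords %*% rotation`), `translation` (length-3), and `rmsd` (Å over
#'   the matched points).
#' @export
kabsch <- function(coords_A, coords_B, weights = NULL) {
  A <- as.matrix(coords_A)
  B <- as.matrix(coords_B)
  if (ncol(A) != 3 || ncol(B) != 3 || nrow(A) != nrow(B)) {
    stop("coordinate sets must be matched n x 3 matrices")
  }
  n <- nrow(A)
  if (n < 3) stop("at least 3 matched points are required")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cA <- colSums(A * w)
  cB <- colSums(B * w)
  A0 <- sweep(A, 2, cA)
  B0 <- sweep(B, 2, cB)
  sv_check <- svd(A0 * sqrt(w))$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1)) {
    stop("degenerate (collinear) point set: superposition is not unique")
  }
  H <- t(A0 * w) %*% B0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)  # x %*% R rotates A-frame into B-frame
  tr <- cB - as.numeric(cA %*% R)
  Afit <- A %*% R + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((Afit - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n = n), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d points: rmsd %.3f Å\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp A `superposition`.
#' @param coords n x 3 matrix in the A-frame.
#' @return Transformed n x 3 matrix in the B-frame.
#' @export
apply_superposition <- function(sp, coords) {
  coords %*% sp$rotation + matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

rmsd_value <- function(X, Y) {
  sqrt(mean(rowSums((X - Y)^2)))
}

#' Structure-based pairwise correspondence between two Ig domains
#'
#' Builds a residue correspondence by iterated superpose-then-match: the
#' current Cα pairing is superposed (Kabsch over the core pairs, i.e. pairs
#' within `trim_cutoff`), all inter-structure Cα distances are scored as
#' `s(i,j) = 1 / (1 + d(i,j)^2 / d0^2)` and re-matched by global dynamic
#' programming with a flat gap penalty (end gaps free, diagonal-preferring
#' tie-break), until the pair set is stable. The seed pairing is plain
#' sequence order.
#'
#' @param A,B `domain_structure` objects with at least 30 Cα atoms each.
#' @param d0 Distance scale of the match score (Å).
#' @param gap_penalty Flat gap penalty in score units.
#' @param trim_cutoff Core-trim cutoff (Å): pairs farther apart than this are
#'   kept in the full correspondence but excluded from the superposition and
#'   flagged non-core.
#' @param max_iter Iteration limit.
#' @param min_pairs Minimum acceptable number of matched pairs.
#' @return A `correspondence` object: data frame `pairs` (local indices
#'   `i`, `j`, residues `aa_i`, `aa_j`, post-superposition distance `dist`,
#'   logical `core`), `percent_identity` over all matched pairs, `rmsd_all`
#'   and `rmsd_core` (Å), the final `superposition`, and `iterations`.
#' @export
structure_align <- function(A, B, d0 = 3, gap_penalty = 0.6,
                            trim_cutoff = 4.5, max_iter = 20,
                            min_pairs = 30) {
  xa <- ca_coords(A)
  xb <- ca_coords(B)
  na <- nrow(xa)
  nb <- nrow(xb)
  if (na < 30 || nb < 30) {
    stop("structure-based alignment needs at least 30 residues with Cα")
  }
  n0 <- min(na, nb)
  pairs <- cbind(seq_len(n0), seq_len(n0))
  prev_key <- ""
  sp <- NULL
  for (iter in seq_len(max_iter)) {
    core <- pairs
    if (!is.null(sp)) {
      d <- sqrt(rowSums((apply_superposition(sp, xa[pairs[, 1], , drop = FALSE]) -
                           xb[pairs[, 2], , drop = FALSE])^2))
      if (sum(d <= trim_cutoff) >= 3) {
        core <- pairs[d <= trim_cutoff, , drop = FALSE]
      }
    }
    sp <- kabsch(xa[core[, 1], , drop = FALSE], xb[core[, 2], , drop = FALSE])
    xa_fit <- apply_superposition(sp, xa)
    dmat <- outer(rowSums(xa_fit^2), rowSums(xb^2), "+") -
      2 * xa_fit %*% t(xb)
    dmat[dmat < 0] <- 0
    smat <- 1 / (1 + dmat / d0^2)
    pairs <- dp_match(smat, gap_penalty)
    key <- paste(pairs[, 1], pairs[, 2], collapse = ";")
    if (identical(key, prev_key)) break
    prev_key <- key
  }
  if (nrow(pairs) < min_pairs) {
    stop("no convergent correspondence with at least ", min_pairs, " pairs")
  }
  d <- sqrt(rowSums((apply_superposition(sp, xa[pairs[, 1], , drop = FALSE]) -
                       xb[pairs[, 2], , drop = FALSE])^2))
  core <- d <= trim_cutoff
  rta <- residue_table(A); rta <- rta[!rta$tag, ]
  rtb <- residue_table(B); rtb <- rtb[!rtb$tag, ]
  ia <- as.integer(rownames(xa))[pairs[, 1]]
  ib <- as.integer(rownames(xb))[pairs[, 2]]
  aa_i <- rta$aa[match(ia, rta$local_index)]
  aa_j <- rtb$aa[match(ib, rtb$local_index)]
  out <- list(
    pairs = data.frame(i = ia, j = ib, aa_i = aa_i, aa_j = aa_j,
                       dist = d, core = core, stringsAsFactors = FALSE),
    percent_identity = 100 * mean(aa_i == aa_j),
    rmsd_all = sqrt(mean(d^2)),
    rmsd_core = sqrt(mean(d[core]^2)),
    superposition = sp,
    iterations = iter,
    labels = c(A$domain_label, B$domain_label)
  )
  class(out) <- "correspondence"
  out
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("correspondence %s/%s: %d pairs (%d core), rmsd %.2f Å, identity %.1f%%\n",
              x$labels[1], x$labels[2], nrow(x$pairs), sum(x$pairs$core),
              x$rmsd_all, x$percent_identity))
  invisible(x)
}

## Global DP over a similarity matrix with flat gap penalty and free end
## gaps; traceback prefers diagonal, then up (gap in B), deterministic.
dp_match <- function(smat, gap_penalty) {
  n <- nrow(smat)
  m <- ncol(smat)
  F <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  for (i in seq_len(n)) {
    frow <- F[i, ]
    newrow <- numeric(m + 1)
    newptr <- integer(m + 1)
    newptr[1] <- 2L
    for (j in seq_len(m)) {
      diag <- frow[j] + smat[i, j]
      up <- frow[j + 1] - if (j == m) 0 else gap_penalty
      left <- newrow[j] - if (i == n) 0 else gap_penalty
      best <- diag; ptr <- 1L
      if (up > best) { best <- up; ptr <- 2L }
      if (left > best) { best <- left; ptr <- 3L }
      newrow[j + 1] <- best
      newptr[j + 1] <- ptr
    }
    F[i + 1, ] <- newrow
    P[i + 1, ] <- newptr
  }
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 && j > 0) {
    p <- P[i + 1, j + 1]
    if (p == 1L) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (p == 2L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  cbind(pi, pj)
}

#' Pairwise RMSD and structure-based identity matrices
#'
#' Runs [structure_align()] for every domain pair and assembles a symmetric
#' RMSD matrix (Å, over each full correspondence) together with the matching
#' structure-based sequence-identity matrix (%), the two quantities the
#' comparative tables juxtapose. Alignment failures are recorded as `NA`
#' entries rather than aborting the matrix.
#'
#' @param domains Named list of `domain_structure` objects (>= 2).
#' @param trim_cutoff Core-trim cutoff in Å passed to [structure_align()].
#' @param ... Further arguments to [structure_align()].
#' @return List with matrices `rmsd` and `identity`, plus `failures`.
#' @export
pairwise_rmsd_matrix <- function(domains, trim_cutoff = 4.5, ...) {
  n <- length(domains)
  if (n < 2) stop("need at least 2 domains")
  labs <- vapply(domains, function(d) d$domain_label, character(1))
  R <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  I <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  diag(R) <- 0
  diag(I) <- 100
  failures <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- tryCatch(structure_align(domains[[i]], domains[[j]],
                                     trim_cutoff = trim_cutoff, ...),
                     error = function(e) e)
      if (inherits(al, "error")) {
        failures <- c(failures, paste0(labs[i], "/", labs[j], ": ",
                                       conditionMessage(al)))
      } else {
        R[i, j] <- R[j, i] <- al$rmsd_all
        I[i, j] <- I[j, i] <- al$percent_identity
      }
    }
  }
  list(rmsd = R, identity = I, failures = failures)
}

#' Per-residue spatial deviation profiles against a reference domain
#'
#' For each non-reference domain, reports the Cα–Cα distance at every aligned
#' reference position after core superposition. Positions above
#' `hotspot_threshold` are flagged as structural-diversity hotspots;
#' unaligned reference positions are reported as gaps (`NA`).
#'
#' @param reference Reference `domain_structure` (conventionally M10, with M7
#'   as the documented alternative).
#' @param others List of `domain_structure` objects to profile.
#' @param hotspot_threshold Distance flagging threshold (Å), default 4.
#' @param ... Further arguments to [structure_align()].
#' @return Named list of data frames (`position`, `aa`, `dist`, `hotspot`),
#'   one per non-reference domain, positions indexed on the reference.
#' @export
deviation_profile <- function(reference, others, hotspot_threshold = 4, ...) {
  rt <- residue_table(reference)
  rt <- rt[!rt$tag, ]
  out <- list()
  for (d in others) {
    prof <- data.frame(position = rt$local_index, aa = rt$aa,
                       dist = NA_real_, hotspot = FALSE,
                       stringsAsFactors = FALSE)
    if (identical(d$domain_label, reference$domain_label) &&
        identical(d$atoms, reference$atoms)) {
      prof$dist <- 0
    } else {
      al <- structure_align(reference, d, ...)
      m <- match(al$pairs$i, prof$position)
      prof$dist[m] <- al$pairs$dist
    }
    prof$hotspot <- !is.na(prof$dist) & prof$dist > hotspot_threshold
    out[[d$domain_label]] <- prof
  }
  out
}

#' RMSD between two determinations of the same domain
#'
#' Self-consistency check for one domain solved in different crystal forms
#' or binding states: residues are matched by identical residue numbering
#' over the common numbered range (no structural dynamic programming), then
#' superposed once.
#'
#' @param formA,formB `domain_structure` objects of the same domain.
#' @return RMSD in Å over the common Cα set.
#' @export
self_consistency_rmsd <- function(formA, formB) {
  xa <- ca_coords(formA)
  xb <- ca_coords(formB)
  common <- intersect(rownames(xa), rownames(xb))
  if (length(common) < 3) stop("fewer than 3 residues in the common numbered range")
  sp <- kabsch(xa[common, , drop = FALSE], xb[common, , drop = FALSE])
  sp$rmsd
}
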