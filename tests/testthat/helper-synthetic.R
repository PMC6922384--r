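## Shared fixtures (memoized: the default fold and the six-fold comparative
## set are built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

default_fold <- function() {
  if (is.null(.fixtures$fold)) {
    .fixtures$fold <- generate_fold(synthetic_fold_spec())
  }
  .fixtures$fold
}

## six-fold comparative set: same idealized architecture, different seeds
## (hence sequences), small per-domain differences in loops and planted
## cysteines, emulating a family of identically folded domains
sixfold_specs <- function() {
  list(
    S1 = synthetic_fold_spec(seed = 11, cysteine_plan = list(
      list(strand = "B", offset = 3, orientation = "in"),
      list(strand = "F", offset = 4, orientation = "in"))),
    S2 = synthetic_fold_spec(seed = 12, loop_lengths = c(6, 9, 5, 3, 7, 3, 7, 4),
                             cysteine_plan = list(
                               list(strand = "A'", offset = 2, orientation = "out"))),
    S3 = synthetic_fold_spec(seed = 13,
                             strand_lengths = c(5, 5, 7, 7, 5, 7, 7, 7, 5)),
    S4 = synthetic_fold_spec(seed = 14, loop_lengths = c(6, 9, 4, 4, 7, 3, 7, 4)),
    S5 = synthetic_fold_spec(seed = 15),
    S6 = synthetic_fold_spec(seed = 16, cysteine_plan = list(
      list(strand = "G", offset = 3, orientation = "out")))
  )
}

sixfold_set <- function() {
  if (is.null(.fixtures$six)) {
    specs <- sixfold_specs()
    .fixtures$six <- lapply(names(specs), function(n) {
      generate_fold(specs[[n]], domain_label = n)
    })
    names(.fixtures$six) <- names(specs)
  }
  .fixtures$six
}

## tiny single-residue-resolution domain built directly from an atom table
raw_domain <- function(atoms, label = "raw") {
  atoms$type <- atoms$type %||% "ATOM"
  defaults <- list(eleno = seq_len(nrow(atoms)), alt = "", resid = "ALA",
                   chain = "A", insert = "", o = 1, b = 0, tag = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (is.null(atoms$local_index)) atoms$local_index <- atoms$resno
  out <- list(domain_label = label, pdb_id = "synthetic", source_chain = "A",
              model_number = 1L, atoms = atoms,
              hetero = atoms[0, , drop = FALSE],
              numbering = list(offset = NA_integer_, uniprot_id = NA_character_))
  class(out) <- "domain_structure"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- independent oracles --------------------------------------------------

## Rotation-grid superposition oracle: coarse Euler-angle grid followed by
## deterministic local grid refinement; never uses the SVD route.
grid_superpose_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  eval_r <- function(a, b, c) {
    sqrt(mean(rowSums((A0 %*% rot(a, b, c) - B0)^2)))
  }
  best <- c(0, 0, 0)
  bv <- Inf
  step <- pi / 18
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (c in seq(0, 2 * pi - step, by = step)) {
        v <- eval_r(a, b, c)
        if (v < bv) { bv <- v; best <- c(a, b, c) }
      }
  for (round in 1:5) {
    step <- step * 0.25
    grid <- seq(-2, 2) * step
    for (da in grid) for (db in grid) for (dc in grid) {
      v <- eval_r(best[1] + da, best[2] + db, best[3] + dc)
      if (v < bv) { bv <- v; best2 <- c(best[1] + da, best[2] + db, best[3] + dc) }
    }
    if (exists("best2")) { best <- best2; rm(best2) }
  }
  bv
}

## Quadrature oracle for the accessible area of one sphere occluded by
## others: Gauss-style latitude-longitude integration (area weights), a
## different numerical route than the spiral point lattice.
quadrature_asa <- function(centers, radii, which_atom, probe = 1.4,
                           n_theta = 200, n_phi = 400) {
  i <- which_atom
  R <- radii[i] + probe
  ct <- seq(-1 + 1 / n_theta, 1 - 1 / n_theta, length.out = n_theta)
  st <- sqrt(1 - ct^2)
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  wt <- (2 / n_theta) * (2 * pi / n_phi) * R^2  # equal-area weight
  acc <- 0
  others <- setdiff(seq_len(nrow(centers)), i)
  for (ti in seq_len(n_theta)) {
    pts <- cbind(R * st[ti] * cos(phis), R * st[ti] * sin(phis),
                 R * ct[ti])
    pts <- sweep(pts, 2, centers[i, ], "+")
    ok <- rep(TRUE, n_phi)
    for (j in others) {
      d2 <- rowSums(sweep(pts, 2, centers[j, ])^2)
      ok <- ok & d2 >= (radii[j] + probe)^2
    }
    acc <- acc + sum(ok) * wt
  }
  acc
}

## Kabsch-Sander energy recomputed with independent arithmetic.
ks_energy_oracle <- function(rON, rCH, rOH, rCN) {
  q1q2 <- 0.42 * 0.20
  f <- 332
  0.084 / (0.42 * 0.20) * q1q2 * f * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

## All-pairs H-bond oracle: applies the stated criterion to every ordered
## residue pair of a domain with no candidate prefilter or per-donor cap.
allpairs_hbond_oracle <- function(domain, cutoff = -0.5) {
  a <- domain$atoms
  idx <- sort(unique(a$local_index))
  coord <- function(i, name) {
    r <- a[a$local_index == i & a$elety == name, c("x", "y", "z")]
    if (nrow(r) == 0) return(NULL)
    as.numeric(r[1, ])
  }
  res3 <- vapply(idx, function(i) a$resid[a$local_index == i][1], character(1))
  bonds <- NULL
  for (di in seq_along(idx)) {
    if (di == 1 || res3[di] == "PRO") next
    N <- coord(idx[di], "N"); CA <- coord(idx[di], "CA")
    Cp <- coord(idx[di - 1], "C")
    if (is.null(N) || is.null(CA) || is.null(Cp)) next
    u1 <- (N - Cp) / sqrt(sum((N - Cp)^2))
    u2 <- (N - CA) / sqrt(sum((N - CA)^2))
    H <- N + (u1 + u2) / sqrt(sum((u1 + u2)^2))
    for (aj in seq_along(idx)) {
      if (abs(idx[di] - idx[aj]) < 2) next
      C <- coord(idx[aj], "C"); O <- coord(idx[aj], "O")
      if (is.null(C) || is.null(O)) next
      e <- 0.084 * 332 * (1 / sqrt(sum((N - O)^2)) + 1 / sqrt(sum((C - H)^2)) -
                            1 / sqrt(sum((O - H)^2)) - 1 / sqrt(sum((C - N)^2)))
      if (e < cutoff) bonds <- rbind(bonds, c(idx[di], idx[aj]))
    }
  }
  bonds
}

## Brute-force global affine-gap alignment score by full enumeration of all
## alignments (sequences of length <= 7); gap run of length L costs
## open + L * extend, matching the affine convention of the implementation.
enumerate_nw_score <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, gapstate) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + sub[av[i], bv[j]], 0L)
    }
    if (i <= length(av)) {  # gap in b
      pen <- extend + if (gapstate == 1L) 0 else open
      rec(i + 1, j, score - pen, 1L)
    }
    if (j <= length(bv)) {  # gap in a
      pen <- extend + if (gapstate == 2L) 0 else open
      rec(i, j + 1, score - pen, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

## dense pH-grid argmin-|charge| oracle for the isoelectric point
grid_pi_oracle <- function(sequence, step = 1e-4) {
  aa <- strsplit(sequence, "")[[1]]
  counts <- table(aa)
  cnt <- function(x) if (x %in% names(counts)) as.numeric(counts[[x]]) else 0
  pH <- seq(0, 14, by = step)
  pos <- 1 / (1 + 10^(pH - 7.5)) +
    cnt("K") / (1 + 10^(pH - 10)) +
    cnt("R") / (1 + 10^(pH - 12)) +
    cnt("H") / (1 + 10^(pH - 5.98))
  neg <- 1 / (1 + 10^(3.55 - pH)) +
    cnt("D") / (1 + 10^(4.05 - pH)) +
    cnt("E") / (1 + 10^(4.45 - pH)) +
    cnt("C") / (1 + 10^(9.0 - pH)) +
    cnt("Y") / (1 + 10^(10.0 - pH))
  pH[which.min(abs(pos - neg))]
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_domain <- function(domain, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(domain$atoms[, c("x", "y", "z")]) %*% R +
    matrix(t, nrow(domain$atoms), 3, byrow = TRUE)
  domain$atoms$x <- xyz[, 1]
  domain$atoms$y <- xyz[, 2]
  domain$atoms$z <- xyz[, 3]
  domain
}

AA_ALPHABET_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
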