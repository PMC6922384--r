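VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

## Maximum accessible surface area of the cysteine side chain (Å²), the
## normalizer used for relative cysteine accessibility throughout.
CYS_MAX_SC_ASA <- 46.6

## Theoretical maximum residue ASA (Å², Tien et al. 2013), used for the
## per-residue relative accessibility behind variant-site classification.
MAX_RES_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

#' Solvent-accessible surface area (Shrake–Rupley)
#'
#' Per-atom accessible surface area from deterministic uniform sphere
#' sampling with a golden-angle spiral lattice (no random numbers, so the
#' result is exactly reproducible and seed-independent). Hydrogens are
#' excluded; hetero-atoms and waters neither receive area nor occlude by
#' default.
#'
#' @param x A `domain_structure` or `structure_model`.
#' @param probe_radius Solvent probe radius (Å), default 1.4.
#' @param n_points Sphere sample points per atom, default 960.
#' @return The atom table of `x` with an `asa` column (Å²).
#' @export
shrake_rupley <- function(x, probe_radius = 1.4, n_points = 960) {
  atoms <- x$atoms
  atoms$elesy <- toupper(trimws(atoms$elesy))
  atoms <- atoms[atoms$elesy != "H", , drop = FALSE]
  elem <- atoms$elesy
  unknown <- !(elem %in% names(VDW_RADII))
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elem[unknown]), collapse = ", "),
            "; using default radius 1.70 Å")
  }
  radii <- ifelse(unknown, 1.70, VDW_RADII[elem])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  sphere <- spiral_points(n_points)
  n <- nrow(xyz)
  ext <- radii + probe_radius
  asa <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sphere * ext[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ext[i] + ext)^2 & d2 > 0)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj2 >= ext[j]^2
    }
    asa[i] <- 4 * pi * ext[i]^2 * sum(acc) / n_points
  }
  atoms$asa <- asa
  atoms
}

## Deterministic golden-angle spiral lattice on the unit sphere.
spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * k
  cbind(r * cos(phi), r * sin(phi), z)
}

sidechain_atoms <- function(atoms) {
  !(atoms$elety %in% c("N", "CA", "C", "O", "OXT")) & atoms$elesy != "H"
}

#' Cysteine exposure and redox classification
#'
#' Computes the side-chain accessible surface of every cysteine (atoms from
#' CB outward), expresses it relative to the 46.6 Å² cysteine side-chain
#' maximum, and classifies each residue: `potential-SS-bridge` when another
#' cysteine SG lies within `ss_cutoff` in the same chain (the pair and its
#' SG–SG distance are reported), otherwise `exposed` when the relative
#' accessibility reaches `exposure_threshold`, otherwise `core-oriented`
#' (sulfhydryl pointing into the hydrophobic core).
#'
#' @param domain A `domain_structure`.
#' @param asa Atom table with `asa` from [shrake_rupley()]; computed if
#'   missing.
#' @param exposure_threshold Relative accessibility threshold in %, default 5.
#' @param ss_cutoff SG–SG distance for disulfide potential (Å), default 4.5.
#' @return A list: `report` data frame (local_index, global (if numbered),
#'   sidechain_asa, relative_accessibility, class, partner, sg_sg_distance)
#'   and counts `n_total`, `n_accessible`.
#' @export
classify_cysteines <- function(domain, asa = NULL, exposure_threshold = 5,
                               ss_cutoff = 4.5) {
  if (is.null(asa)) asa <- shrake_rupley(domain)
  rt <- residue_table(domain)
  cys <- rt$local_index[rt$resid == "CYS"]
  if (!length(cys)) {
    return(list(report = data.frame(local_index = integer(),
                                    sidechain_asa = numeric(),
                                    relative_accessibility = numeric(),
                                    class = character(),
                                    partner = integer(),
                                    sg_sg_distance = numeric()),
                n_total = 0L, n_accessible = 0L))
  }
  sg <- asa[asa$elety == "SG", , drop = FALSE]
  sc_asa <- vapply(cys, function(i) {
    sel <- asa$local_index == i & sidechain_atoms(asa)
    sum(asa$asa[sel])
  }, numeric(1))
  rel <- 100 * sc_asa / CYS_MAX_SC_ASA
  partner <- rep(NA_integer_, length(cys))
  sgdist <- rep(NA_real_, length(cys))
  if (nrow(sg) >= 2) {
    for (a in seq_along(cys)) {
      pa <- sg[sg$local_index == cys[a], c("x", "y", "z")]
      if (nrow(pa) == 0) next
      best <- NA_integer_; bd <- Inf
      for (b in seq_along(cys)) {
        if (b == a) next
        pb <- sg[sg$local_index == cys[b], c("x", "y", "z")]
        if (nrow(pb) == 0) next
        d <- sqrt(sum((as.numeric(pa[1, ]) - as.numeric(pb[1, ]))^2))
        if (d < bd) { bd <- d; best <- cys[b] }
      }
      if (!is.na(best) && bd <= ss_cutoff) {
        partner[a] <- best
        sgdist[a] <- bd
      }
    }
  }
  class <- ifelse(!is.na(partner), "potential-SS-bridge",
                  ifelse(rel >= exposure_threshold, "exposed", "core-oriented"))
  rep_df <- data.frame(
    local_index = cys,
    sidechain_asa = sc_asa,
    relative_accessibility = rel,
    class = class,
    partner = partner,
    sg_sg_distance = sgdist,
    stringsAsFactors = FALSE
  )
  if (!is.na(domain$numbering$offset)) {
    rep_df$global <- local_to_global(domain, cys)
  }
  list(report = rep_df,
       n_total = length(cys),
       n_accessible = sum(rel >= exposure_threshold))
}

#' Intra- and intermolecular disulfide detection
#'
#' Lists all cysteine SG–SG pairs in a multi-chain model: pairs at or below
#' `formed_cutoff` are labelled `formed` (a covalent bridge), pairs between
#' that and `potential_cutoff` are labelled `potential` (reduced cysteines
#' positioned for bridge formation). Chain ids distinguish intra- from
#' intermolecular pairs.
#'
#' @param model A `structure_model`.
#' @param formed_cutoff Distance for a formed bridge (Å), default 2.5.
#' @param potential_cutoff Upper distance for a potential bridge (Å),
#'   default 4.5.
#' @return Data frame: chains, residue numbers, `distance`, `status`
#'   (`formed`/`potential`), `scope` (`intra`/`inter`).
#' @export
detect_disulfides <- function(model, formed_cutoff = 2.5,
                              potential_cutoff = 4.5) {
  sg <- model$atoms[model$atoms$elety == "SG" & model$atoms$resid == "CYS", ,
                    drop = FALSE]
  out <- data.frame(chain_a = character(), resno_a = integer(),
                    chain_b = character(), resno_b = integer(),
                    distance = numeric(), status = character(),
                    scope = character(), stringsAsFactors = FALSE)
  if (nrow(sg) < 2) return(out)
  for (a in seq_len(nrow(sg) - 1)) {
    for (b in seq(a + 1, nrow(sg))) {
      d <- sqrt(sum((as.numeric(sg[a, c("x", "y", "z")]) -
                       as.numeric(sg[b, c("x", "y", "z")]))^2))
      if (d > potential_cutoff) next
      out <- rbind(out, data.frame(
        chain_a = sg$chain[a], resno_a = sg$resno[a],
        chain_b = sg$chain[b], resno_b = sg$resno[b],
        distance = d,
        status = if (d <= formed_cutoff) "formed" else "potential",
        scope = if (sg$chain[a] == sg$chain[b]) "intra" else "inter",
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}

METAL_ELEMENTS <- c("ZN", "FE", "MG", "MN", "CU", "NI", "CO", "CD", "CA", "K",
                    "NA", "HG", "RB", "CS", "SR", "BA")

#' Metal-site detection and coordination geometry
#'
#' For every mono-atomic metal hetero-atom in the model, collects protein
#' N/O/S ligand atoms within `coordination_cutoff` and classifies the
#' coordination geometry as tetrahedral when exactly four ligands subtend
#' ligand–metal–ligand angles within `angle_tol` of 109.5°.
#'
#' @param model A `structure_model` with a hetero-atom table.
#' @param coordination_cutoff Ligand distance cutoff (Å), default 2.8.
#' @param angle_tol Allowed deviation from the ideal tetrahedral angle
#'   (degrees), default 20.
#' @return List of metal sites, each with `metal`, `position`, `ligands`
#'   (data frame: chain, resno, resid, elety, distance) and `geometry`.
#' @export
detect_metal_sites <- function(model, coordination_cutoff = 2.8,
                               angle_tol = 20) {
  het <- model$hetero
  if (is.null(het) || nrow(het) == 0) return(list())
  metals <- het[toupper(trimws(het$elesy)) %in% METAL_ELEMENTS &
                  het$resid != "HOH", , drop = FALSE]
  prot <- model$atoms[model$atoms$elesy %in% c("N", "O", "S"), , drop = FALSE]
  sites <- list()
  for (m in seq_len(nrow(metals))) {
    mp <- as.numeric(metals[m, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(as.matrix(prot[, c("x", "y", "z")]), 2, mp)^2))
    lig <- prot[d <= coordination_cutoff, , drop = FALSE]
    lig$distance <- d[d <= coordination_cutoff]
    geometry <- "other"
    if (nrow(lig) == 4) {
      vs <- sweep(as.matrix(lig[, c("x", "y", "z")]), 2, mp)
      vs <- vs / sqrt(rowSums(vs^2))
      angs <- c()
      for (a in 1:3) for (b in (a + 1):4) {
        angs <- c(angs, acos(pmin(1, pmax(-1, sum(vs[a, ] * vs[b, ])))) * 180 / pi)
      }
      if (all(abs(angs - 109.5) <= angle_tol)) geometry <- "tetrahedral"
    }
    sites[[length(sites) + 1]] <- list(
      metal = toupper(trimws(metals$elesy[m])),
      position = mp,
      ligands = lig[, c("chain", "resno", "resid", "elety", "distance")],
      geometry = geometry
    )
  }
  sites
}

## Bjellqvist pKa set (as used for ProtParam-style pI values).
PI_PKA <- list(
  nterm = 7.5, cterm = 3.55,
  pos = c(K = 10.0, R = 12.0, H = 5.98),
  neg = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

#' Isoelectric point (Bjellqvist pKa set)
#'
#' Net charge as a function of pH from Henderson–Hasselbalch terms for the
#' termini and ionizable side chains, with the pI solved by bisection to
#' `|Z| < 1e-4`.
#'
#' @param sequence Amino-acid string (standard 20 letters).
#' @return pI (pH units).
#' @export
isoelectric_point <- function(sequence) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad)) stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))
  counts <- table(aa)
  z <- function(pH) net_charge(counts, pH)
  lo <- 0; hi <- 14
  ## bisect to the sign change itself (|Z| well below 1e-4): the net-charge
  ## curve can be very flat around the pI, so an |Z| stop alone is too loose
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (z(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

net_charge <- function(counts, pH) {
  cnt <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
  zpos <- 1 / (1 + 10^(pH - PI_PKA$nterm)) +
    sum(vapply(names(PI_PKA$pos), function(a) {
      cnt(a) / (1 + 10^(pH - PI_PKA$pos[[a]]))
    }, numeric(1)))
  zneg <- 1 / (1 + 10^(PI_PKA$cterm - pH)) +
    sum(vapply(names(PI_PKA$neg), function(a) {
      cnt(a) / (1 + 10^(PI_PKA$neg[[a]] - pH))
    }, numeric(1)))
  zpos - zneg
}

#' Per-residue relative accessibility
#'
#' All-atom residue ASA normalized by the theoretical per-residue maximum,
#' as used for variant-site classification.
#'
#' @param domain A `domain_structure`.
#' @param asa Atom table with `asa`; computed if missing.
#' @return Data frame: `local_index`, `residue_asa`, `rel_asa` (%).
#' @export
residue_accessibility <- function(domain, asa = NULL) {
  if (is.null(asa)) asa <- shrake_rupley(domain)
  rt <- residue_table(domain)
  ra <- vapply(rt$local_index, function(i) {
    sum(asa$asa[asa$local_index == i])
  }, numeric(1))
  mx <- MAX_RES_ASA[rt$aa]
  mx[is.na(mx)] <- mean(MAX_RES_ASA)
  data.frame(local_index = rt$local_index, residue_asa = ra,
             rel_asa = 100 * ra / mx)
}
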