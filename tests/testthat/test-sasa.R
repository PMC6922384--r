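test_that("an isolated atom has the closed-form sphere area", {
  d <- raw_domain(data.frame(elety = "SG", resid = "CYS", resno = 1,
                             local_index = 1, x = 0, y = 0, z = 0,
                             elesy = "S"))
  a <- shrake_rupley(d)
  expect_equal(a$asa, 4 * pi * (1.80 + 1.4)^2, tolerance = 1e-6)
  dn <- raw_domain(data.frame(elety = "N", resid = "ALA", resno = 1,
                              local_index = 1, x = 0, y = 0, z = 0,
                              elesy = "N"))
  expect_equal(shrake_rupley(dn)$asa, 4 * pi * (1.55 + 1.4)^2,
               tolerance = 1e-6)
})

test_that("two-atom occlusion matches a quadrature oracle within 2 percent at all separations", {
  radii <- c(1.70, 1.52)
  for (sep in c(1.0, 2.0, 3.0, 4.5, 6.0)) {
    centers <- rbind(c(0, 0, 0), c(sep, 0, 0))
    d <- raw_domain(data.frame(elety = c("CB", "O"), resid = "ALA",
                               resno = c(1, 2), local_index = c(1, 2),
                               x = centers[, 1], y = centers[, 2],
                               z = centers[, 3], elesy = c("C", "O")))
    a <- shrake_rupley(d)
    for (i in 1:2) {
      ref <- quadrature_asa(centers, radii, i)
      expect_equal(a$asa[i], ref, tolerance = 0.02)
    }
  }
})

test_that("accessible area behaves physically: bounded, monotone under approach, stable in n_points", {
  d <- default_fold()
  a <- shrake_rupley(d)
  expect_true(all(a$asa >= 0))
  radii <- ifelse(a$elesy == "S", 1.80,
                  ifelse(a$elesy == "N", 1.55,
                         ifelse(a$elesy == "O", 1.52, 1.70)))
  expect_true(all(a$asa <= 4 * pi * (radii + 1.4)^2 + 1e-9))
  ## total area does not exceed the sum of isolated-atom areas
  expect_lt(sum(a$asa), sum(4 * pi * (radii + 1.4)^2))
  ## a second molecule approaching monotonically decreases the area
  probe_atom <- function(x) {
    dd <- raw_domain(data.frame(elety = c("CB", "CB"), resid = "ALA",
                                resno = c(1, 2), local_index = c(1, 2),
                                x = c(0, x), y = 0, z = 0, elesy = "C"))
    shrake_rupley(dd)$asa[1]
  }
  vals <- vapply(c(8, 6, 4, 3, 2), probe_atom, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  ## doubling the point count changes per-atom areas by < 1% of the sphere
  a2 <- shrake_rupley(d, n_points = 1920)
  sphere <- 4 * pi * (radii + 1.4)^2
  expect_lt(max(abs(a2$asa - a$asa) / sphere), 0.01)
  ## deterministic: identical on repetition
  expect_identical(shrake_rupley(d)$asa, a$asa)
})

test_that("unknown elements fall back to the default radius with a warning", {
  d <- raw_domain(data.frame(elety = "XX", resid = "UNK", resno = 1,
                             local_index = 1, x = 0, y = 0, z = 0,
                             elesy = "X"))
  expect_warning(a <- shrake_rupley(d), "unknown element")
  expect_equal(a$asa, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
})

test_that("planted exposed and buried cysteines are classified as such", {
  spec <- synthetic_fold_spec(cysteine_plan = list(
    list(strand = "B", offset = 3, orientation = "out"),
    list(strand = "F", offset = 4, orientation = "in")))
  d <- generate_fold(spec)
  cys <- classify_cysteines(d)
  expect_equal(cys$n_total, 2L)
  gt <- attr(d, "ground_truth")
  rep <- cys$report[match(gt$cysteines$local_index, cys$report$local_index), ]
  expect_equal(rep$class[gt$cysteines$orientation == "out"], "exposed")
  expect_equal(rep$class[gt$cysteines$orientation == "in"], "core-oriented")
  expect_equal(cys$n_accessible, 1L)
  ## raising the exposure threshold never increases the accessible count
  ths <- c(1, 5, 10, 25, 50, 95)
  ns <- vapply(ths, function(th) {
    classify_cysteines(d, exposure_threshold = th)$n_accessible
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("a cysteine-free domain yields an empty report", {
  d <- generate_fold(synthetic_fold_spec(seed = 55))
  cys <- classify_cysteines(d)
  expect_equal(cys$n_total, 0L)
  expect_equal(cys$n_accessible, 0L)
  expect_equal(nrow(cys$report), 0L)
})

test_that("an intramolecular SG pair within 4.5 A is reported as a potential bridge with its distance", {
  ## two face-to-face cysteines on opposite sheets, SG-SG planted at 4.0 A
  spec <- synthetic_fold_spec(cysteine_plan = list(
    list(strand = "B", offset = 4, orientation = "in"),
    list(strand = "F", offset = 4, orientation = "in")))
  d <- generate_fold(spec)
  sg <- d$atoms[d$atoms$elety == "SG", ]
  ## move the second SG to exactly 4.0 A from the first along their axis
  v <- as.numeric(sg[2, c("x", "y", "z")]) - as.numeric(sg[1, c("x", "y", "z")])
  v <- v / sqrt(sum(v^2))
  newpos <- as.numeric(sg[1, c("x", "y", "z")]) + 4.0 * v
  sel <- d$atoms$elety == "SG" & d$atoms$local_index == sg$local_index[2]
  d$atoms[sel, c("x", "y", "z")] <- as.list(newpos)
  cys <- classify_cysteines(d)
  expect_true(all(cys$report$class == "potential-SS-bridge"))
  expect_equal(cys$report$sg_sg_distance, c(4, 4), tolerance = 1e-6)
  expect_equal(cys$report$partner, rev(cys$report$local_index))
  ## the same pair through the model-level scan
  ss <- detect_disulfides(combine_model(list(d)))
  expect_equal(nrow(ss), 1)
  expect_equal(ss$status, "potential")
  expect_equal(ss$scope, "intra")
  expect_equal(ss$distance, 4, tolerance = 1e-6)
})

test_that("an intermolecular SG pair at bonding distance is reported as formed", {
  dc <- generate_fold(synthetic_fold_spec(cysteine_plan = list(
    list(strand = "B", offset = 3, orientation = "out"))))
  sg <- dc$atoms[dc$atoms$elety == "SG", c("x", "y", "z")]
  ## second copy rotated 180 degrees about the z axis through the SG, so the
  ## two SG atoms land 2.05 A apart across the interface
  ctr <- as.numeric(sg[1, ]) + c(2.05 / 2, 0, 0)
  R <- diag(c(-1, -1, 1))
  d2 <- dc
  xyz <- as.matrix(dc$atoms[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, ctr) %*% R, 2, ctr, "+")
  d2$atoms[, c("x", "y", "z")] <- xyz
  mod <- combine_model(list(dc, d2), chain_ids = c("A", "B"))
  ss <- detect_disulfides(mod)
  inter <- ss[ss$scope == "inter", ]
  expect_equal(nrow(inter), 1)
  expect_equal(inter$status, "formed")
  expect_equal(inter$distance, 2.05, tolerance = 1e-6)
  ## no cysteines -> empty
  d0 <- generate_fold(synthetic_fold_spec(seed = 56))
  expect_equal(nrow(detect_disulfides(combine_model(list(d0)))), 0)
})

test_that("a planted tetrahedral zinc site is detected with four ligands", {
  d <- generate_fold(synthetic_fold_spec(metal_plan = list(element = "ZN",
                                                           loop = "CC'")))
  mod <- combine_model(list(d))
  sites <- detect_metal_sites(mod)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$metal, "ZN")
  expect_equal(sites[[1]]$geometry, "tetrahedral")
  expect_equal(nrow(sites[[1]]$ligands), 4)
  expect_equal(sites[[1]]$ligands$distance, rep(2, 4), tolerance = 1e-6)
  ## model without metals -> empty
  d0 <- generate_fold(synthetic_fold_spec(seed = 57))
  expect_length(detect_metal_sites(combine_model(list(d0))), 0)
})

test_that("the isoelectric point matches a dense pH-grid oracle and known monotonicities", {
  seqs <- c("ACDEFGHIKLMNPQRSTVWY",
            "DDDDEEEE", "KKKKRRRR", "GGGG",
            domain_sequence(default_fold()))
  for (s in seqs) {
    expect_equal(isoelectric_point(s), grid_pi_oracle(s), tolerance = 2e-4)
  }
  base <- "ACDEFGHIKLMNPQRSTVWY"
  expect_gte(isoelectric_point(paste0(base, "R")), isoelectric_point(base))
  expect_lte(isoelectric_point(paste0(base, "D")), isoelectric_point(base))
  expect_error(isoelectric_point("ACDX"), "non-standard")
  expect_error(isoelectric_point(""), "empty")
})
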