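test_that("the electrostatic energy matches independent arithmetic on fixed geometries", {
  ## ideal antiparallel geometry quoted in the acceptance examples
  e <- mbandIg:::ks_energy(2.9, 3.5, 1.9, 3.9)
  expect_equal(e, 0.084 * 332 * (1 / 2.9 + 1 / 3.5 - 1 / 1.9 - 1 / 3.9))
  expect_equal(e, -4.2, tolerance = 0.03)
  set.seed(10)
  for (k in 1:20) {
    r <- runif(4, 1.5, 6)
    expect_equal(mbandIg:::ks_energy(r[1], r[2], r[3], r[4]),
                 max(ks_energy_oracle(r[1], r[2], r[3], r[4]), -9.9),
                 tolerance = 1e-9)
  }
})

test_that("residues far apart form no hydrogen bond", {
  mk_res <- function(i, x0) data.frame(
    elety = c("N", "CA", "C", "O"), resno = i, local_index = i,
    x = x0 + c(0, 1.2, 2.2, 2.2), y = c(0, 0.9, 0.2, 1.4), z = 0,
    resid = "ALA", elesy = c("N", "C", "C", "O"))
  d <- raw_domain(rbind(mk_res(1, 0), mk_res(2, 3.6), mk_res(3, 20),
                        mk_res(4, 23.6)))
  hb <- detect_hbonds(d)
  expect_true(all(abs(hb$donor - hb$acceptor) < 3) || nrow(hb) == 0)
  expect_false(any(abs(hb$donor - hb$acceptor) >= 3))
})

test_that("the detected ladder equals an exhaustive all-pairs oracle on generated folds", {
  d <- default_fold()
  hb <- detect_hbonds(d)
  oracle <- allpairs_hbond_oracle(d)
  key_imp <- paste(hb$donor, hb$acceptor)
  key_or <- paste(oracle[, 1], oracle[, 2])
  ## the implementation caps acceptors per donor at two; the oracle has no
  ## cap, so implementation bonds are a subset, and equality must hold for
  ## donors with at most two oracle bonds
  expect_true(all(key_imp %in% key_or))
  per_donor <- table(oracle[, 1])
  uncapped <- names(per_donor)[per_donor <= 2]
  expect_setequal(key_imp[hb$donor %in% as.integer(uncapped)],
                  key_or[oracle[, 1] %in% as.integer(uncapped)])
})

test_that("proline never donates and incomplete backbones are skipped with a warning", {
  d <- default_fold()
  rt <- residue_table(d)
  pro <- rt$local_index[rt$resid == "PRO"]
  if (length(pro)) {
    hb <- detect_hbonds(d)
    expect_false(any(hb$donor %in% pro))
  }
  broken <- d
  drop_idx <- 30
  broken$atoms <- broken$atoms[!(broken$atoms$local_index == drop_idx &
                                   broken$atoms$elety == "O"), ]
  expect_warning(detect_hbonds(broken), "incomplete")
})

test_that("the nine Ig strands and both sheets are recovered from the generated fold", {
  d <- default_fold()
  topo <- assign_topology(d)
  expect_equal(nrow(topo$strands), 9)
  expect_equal(topo$strands$label,
               c("A", "A'", "B", "C", "C'", "D", "E", "F", "G"))
  expect_setequal(unique(topo$strands$sheet_name), c("ABDE", "A'CC'FG"))
  gt <- attr(d, "ground_truth")
  ## every detected strand lies inside its planted range with matching label
  for (s in seq_len(9)) {
    planted <- gt$strand_ranges[gt$strand_ranges$label == topo$strands$label[s], ]
    expect_gte(topo$strands$from[s], planted$from)
    expect_lte(topo$strands$to[s], planted$to)
  }
  ## sheet membership matches the planted architecture
  planted_sheet <- gt$strand_ranges$sheet[match(topo$strands$label,
                                                gt$strand_ranges$label)]
  expect_true(all((topo$strands$sheet_name == "ABDE") == (planted_sheet == 1)))
})

test_that("the EF-loop 3-10 helix is detected where planted and only there", {
  d <- default_fold()
  topo <- assign_topology(d)
  expect_true(topo$has_310)
  gt <- attr(d, "ground_truth")
  got <- topo$residues$local_index[topo$residues$state == "3-10"]
  expect_true(all(gt$helix_310 %in% got))
  ## all detected 3-10 residues sit inside the EF loop
  ef <- gt$loop_ranges[gt$loop_ranges$loop == "EF", ]
  expect_true(all(got %in% (ef$from - 1):(ef$to + 1)))
  ## a fold built without the helical segment has none
  d0 <- generate_fold(synthetic_fold_spec(helix_310 = FALSE, seed = 41))
  expect_false(assign_topology(d0)$has_310)
})

test_that("an isolated hairpin yields two strands in one sheet and no helix", {
  ## carve the D-E hairpin out of the generated fold
  d <- default_fold()
  gt <- attr(d, "ground_truth")
  rng <- range(gt$strand_ranges[gt$strand_ranges$label %in% c("D", "E"),
                                c("from", "to")])
  hp <- d
  hp$atoms <- d$atoms[d$atoms$local_index %in% rng[1]:rng[2], , drop = FALSE]
  topo <- suppressWarnings(assign_topology(hp))
  expect_equal(nrow(topo$strands), 2)
  expect_equal(length(unique(topo$strands$sheet)), 1)
  expect_false(topo$has_310)
  expect_warning(assign_topology(hp), "best-effort")
})

test_that("loop naming and tip assignment follow the Ig convention", {
  topo <- assign_topology(default_fold())
  rr <- topo$residues
  tips <- unique(rr[!is.na(rr$tip), c("loop_name", "tip")])
  expect_setequal(tips$loop_name[tips$tip == "N-tip"],
                  c("BC", "DE", "FG"))
  expect_setequal(tips$loop_name[tips$tip == "C-tip"],
                  c("A'B", "C'D", "EF"))
})

test_that("identical copies give all-6/6 hydrogen-bond conservation and a planted missing rung is 5/6", {
  d <- default_fold()
  copies <- list(C1 = d, C2 = d, C3 = d, C4 = d, C5 = d, C6 = d)
  for (n in names(copies)) copies[[n]]$domain_label <- n
  master <- build_master_alignment(copies, reference = "C1")
  cons <- hbond_conservation(copies, master)
  expect_true(all(cons$table$count == 6))
  expect_true(all(cons$table$class == "6/6"))
  expect_gt(cons$per_sheet[["ABDE"]], 0)
  expect_gt(cons$per_sheet[["A'CC'FG"]], 0)

  ## break one rung in one copy: push one E-strand residue's O far away
  gt <- attr(d, "ground_truth")
  hb <- detect_hbonds(d)
  estrand <- gt$strand_ranges[gt$strand_ranges$label == "E", ]
  mid <- floor((estrand$from + estrand$to) / 2)
  cand <- hb[hb$donor == mid & abs(hb$donor - hb$acceptor) > 4, ][1, ]
  broken <- copies
  sel <- broken$C6$atoms$local_index == cand$acceptor &
    broken$C6$atoms$elety == "O"
  broken$C6$atoms$z[sel] <- broken$C6$atoms$z[sel] + 30
  cons2 <- hbond_conservation(broken, master)
  key <- paste(cons2$table$col_donor, cons2$table$col_acceptor)
  k5 <- cons2$table$count[key == paste(cand$donor, cand$acceptor)]
  expect_true(all(k5 <= 5))
  expect_true(any(cons2$table$count == 5))
})

test_that("conservation counts are invariant to the order of input structures", {
  doms <- sixfold_set()
  master <- build_master_alignment(doms, reference = "S1")
  c1 <- hbond_conservation(doms, master)
  c2 <- hbond_conservation(rev(doms), master)
  expect_equal(c1$per_sheet[sort(names(c1$per_sheet))],
               c2$per_sheet[sort(names(c2$per_sheet))])
  t1 <- c1$table[order(c1$table$col_donor, c1$table$col_acceptor),
                 c("col_donor", "col_acceptor", "count")]
  t2 <- c2$table[order(c2$table$col_donor, c2$table$col_acceptor),
                 c("col_donor", "col_acceptor", "count")]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})
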