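test_that("global alignment of a sequence with itself is gap-free at 100% identity", {
  s <- domain_sequence(default_fold())
  al <- needleman_wunsch(s, s)
  expect_equal(al$identity, 100)
  expect_false(grepl("-", al$aligned_a))
  expect_error(needleman_wunsch("", "ACDE"), "non-empty")
})

test_that("alignment scores equal the brute-force enumeration optimum on short pairs", {
  set.seed(12)
  ## fixed random panel of 60 pairs of length <= 7 plus the quoted example
  pairs <- c(list(c("ACDE", "ACE")), lapply(1:60, function(k) {
    c(paste(sample(AA_ALPHABET_TEST, sample(2:7, 1), replace = TRUE), collapse = ""),
      paste(sample(AA_ALPHABET_TEST, sample(2:7, 1), replace = TRUE), collapse = ""))
  }))
  for (p in pairs) {
    expect_equal(needleman_wunsch(p[1], p[2])$score,
                 enumerate_nw_score(p[1], p[2]),
                 tolerance = 1e-9, label = paste(p, collapse = "/"))
  }
})

test_that("queries are assigned to the human domain of highest identity", {
  set.seed(13)
  humans <- vapply(1:5, function(k) {
    paste(sample(AA_ALPHABET_TEST, 40, replace = TRUE), collapse = "")
  }, character(1))
  names(humans) <- paste0("M", c(1, 3, 4, 7, 10))
  ## self-assignment
  res <- assign_domains_by_identity(humans, humans)
  expect_equal(res$domain, names(humans))
  expect_equal(res$identity, rep(100, 5))
  ## a 80%-identity mutant of M10 still maps to M10
  m <- strsplit(humans[["M10"]], "")[[1]]
  mut_at <- seq(1, 40, by = 5)
  for (i in mut_at) m[i] <- setdiff(AA_ALPHABET_TEST, m[i])[1]
  res2 <- assign_domains_by_identity(c(q = paste(m, collapse = "")), humans)
  expect_equal(res2$domain, "M10")
})

test_that("identity colour classes follow the published thresholds", {
  ## toy 10-residue pair with 7 matches -> 70%, class yellow
  panel <- list(D1 = c(human = "ACDEFGHIKL", mouse = "ACDEFGHWWW"))
  cs <- cross_species_identity(panel)
  expect_equal(cs$identity[cs$species == "mouse"], 70)
  expect_equal(cs$class[cs$species == "mouse"], "yellow")
  expect_equal(cs$class[cs$species == "human"], "red")
  ## boundary behaviour with isolated substitutions (gaps never pay):
  ## 25 scattered mismatches in 100 -> 75%, orange; 10 -> 90%, red
  human <- paste(rep("A", 100), collapse = "")
  sub_at <- function(pos) {
    v <- rep("A", 100); v[pos] <- "W"; paste(v, collapse = "")
  }
  p2 <- list(D1 = c(human = human, sp = sub_at(seq(2, 98, by = 4))))
  expect_equal(cross_species_identity(p2)$identity[2], 75)
  expect_equal(cross_species_identity(p2)$class[2], "orange")
  p3 <- list(D1 = c(human = human, sp = sub_at(seq(5, 95, by = 10))))
  expect_equal(cross_species_identity(p3)$class[2], "red")
})

test_that("the master alignment of a single domain is the identity, and of a copy is gap-free", {
  d <- default_fold()
  ma1 <- build_master_alignment(list(REF = d), reference = "REF")
  expect_equal(nrow(ma1$columns), n_residues(d))
  expect_equal(ma1$columns$REF_idx, seq_len(n_residues(d)))
  expect_true(all(ma1$columns$REF_certain))
  cp <- d
  ma2 <- build_master_alignment(list(REF = d, COPY = cp), reference = "REF")
  expect_equal(nrow(ma2$columns), n_residues(d))
  expect_equal(ma2$columns$COPY_idx, ma2$columns$REF_idx)
  fa <- master_alignment_fasta(ma2)
  expect_false(grepl("-", fa[["COPY"]]))
})

test_that("master-alignment columns are consistent with pairwise correspondences", {
  doms <- sixfold_set()
  ma <- build_master_alignment(doms, reference = "S1")
  cols <- ma$columns
  for (lab in names(doms)) {
    idx <- cols[[paste0(lab, "_idx")]]
    idx <- idx[!is.na(idx)]
    ## each residue appears in at most one column, in increasing order
    expect_false(any(duplicated(idx)))
    expect_true(all(diff(idx) > 0))
  }
  ## anchored placements match the pairwise correspondence to the reference
  al <- structure_align(doms$S1, doms$S3)
  placed <- cols[, c("S1_idx", "S3_idx")]
  placed <- placed[!is.na(placed$S1_idx) & !is.na(placed$S3_idx), ]
  key_master <- paste(placed$S1_idx, placed$S3_idx)
  key_pair <- paste(al$pairs$i, al$pairs$j)
  expect_true(all(key_master %in% key_pair))
})

test_that("planted conservation structure is recovered from a synthetic family and species panel", {
  base <- paste(rep("ACDEFGHIKLMNQRSTVWYG", 4), collapse = "")
  fam <- generate_family(synthetic_family_spec(
    base, n_members = 6,
    invariant_columns = c(5, 33, 61),
    signature_columns = list(`12` = c("W", "Y", "F", "H", "K", "D"),
                             `14` = c("D", "E", "N", "Q", "S", "T"),
                             `27` = c("I", "L", "V", "M", "F", "A")),
    mutation_rate = 0.5, seed = 3))
  ## the species substitution rate is set high enough that unconstrained
  ## columns are essentially never invariant across all species of all six
  ## members, so the planted categories are identifiable
  panel <- generate_species_panel(
    as.list(fam$sequences), frozen_columns = c(5, 12, 14, 27, 33, 61),
    species_rate = 0.35, seed = 4)
  ## sequence-only master alignment: members are equal length and ungapped
  doms <- names(fam$sequences)
  cols <- data.frame(column = seq_len(nchar(base)),
                     ref_index = seq_len(nchar(base)))
  for (m in doms) {
    cols[[paste0(m, "_idx")]] <- cols$column
    cols[[paste0(m, "_aa")]] <- strsplit(fam$sequences[[m]], "")[[1]]
    cols[[paste0(m, "_certain")]] <- TRUE
  }
  ma <- structure(list(columns = cols, reference = doms[1], labels = doms),
                  class = "master_alignment")
  cc <- classify_columns(ma, panel = panel)
  ## planted invariants recovered (100% recall)
  expect_true(all(cc$categories[c(5, 33, 61)] == "invariant"))
  ## planted signature columns recovered exactly
  sig <- which(cc$categories == "domain_specific_signature")
  expect_setequal(sig, c(12, 14, 27))
  ## all-identical family: every column invariant
  fam0 <- generate_family(synthetic_family_spec(base, n_members = 4,
                                                mutation_rate = 0, seed = 5))
  expect_true(all(fam0$sequences == base))
  cols0 <- cols[, 1:2]
  for (m in paste0("member_", 1:4)) {
    cols0[[paste0(m, "_idx")]] <- cols0$column
    cols0[[paste0(m, "_aa")]] <- strsplit(base, "")[[1]]
    cols0[[paste0(m, "_certain")]] <- TRUE
  }
  ma0 <- structure(list(columns = cols0, reference = "member_1",
                        labels = paste0("member_", 1:4)),
                   class = "master_alignment")
  expect_true(all(classify_columns(ma0)$categories == "invariant"))
})

test_that("category counts respond monotonically to enlarging the conserved groups", {
  doms <- sixfold_set()
  ma <- build_master_alignment(doms, reference = "S1")
  small_groups <- list(c("I", "L"), c("D", "E"))
  big_groups <- list(c("I", "L", "V", "M", "F", "Y", "W", "A"),
                     c("D", "E", "N", "Q", "S", "T"),
                     c("K", "R", "H"))
  n_small <- classify_columns(ma, conserved_groups = small_groups)$counts[["conserved"]]
  n_big <- classify_columns(ma, conserved_groups = big_groups)$counts[["conserved"]]
  expect_gte(n_big, n_small)
})

test_that("column classification is invariant to domain input order", {
  doms <- sixfold_set()
  ma <- build_master_alignment(doms, reference = "S1")
  c1 <- classify_columns(ma)
  ma_rev <- ma
  ma_rev$labels <- rev(ma$labels)
  c2 <- classify_columns(ma_rev)
  expect_equal(c1$categories, c2$categories)
})

test_that("FASTA sequences round-trip through the writers", {
  seqs <- c(a = "ACDEFG", b = "KLMNPQ")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, f)
  expect_equal(read_fasta_sequences(f), seqs)
})
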