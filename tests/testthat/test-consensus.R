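test_that("column profiles tally homologs only, at reference columns only", {
  aln <- msa_alignment(c("REF", "H1", "H2", "H3", "H4"),
                       c("AC-DE", "AKX-E", "AK-DE", "GK--E", "-KCD-"),
                       "REF")
  prof <- column_profiles(aln)
  ## reference has a gap at column 3 -> profiles only for columns 1,2,4,5
  expect_equal(nrow(prof), 4)
  expect_equal(prof$column_index, c(0L, 1L, 3L, 4L))
  expect_equal(prof$ref_position, 1:4)
  expect_equal(prof$ref_residue, c("A", "C", "D", "E"))
  ## column 1: homologs A,A,G,- -> counts A=2, G=1; coverage 3/4
  expect_equal(prof$n_A[1], 2L)
  expect_equal(prof$n_G[1], 1L)
  expect_equal(prof$coverage[1], 3 / 4)
  ## column 2: homologs K,K,K,K
  expect_equal(prof$n_K[2], 4L)
  expect_equal(prof$coverage[2], 1)
  ## count conservation: counts + gaps + X = n_homologs at every column
  counts <- rowSums(as.matrix(prof[, paste0("n_", c("A", "C", "D", "E", "F",
    "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W",
    "Y"))]))
  m <- do.call(rbind, strsplit(unname(aln$seqs[-1]), ""))
  gaps_x <- vapply(prof$column_index + 1, function(j)
    sum(m[, j] %in% c("-", "X")), numeric(1))
  expect_equal(counts + gaps_x, rep(4, 4))
})

test_that("profiles match a brute-force tally on a toy 4-homolog MSA", {
  withr::with_seed(42, {
    aln <- random_small_msa(5, 8, gap_prob = 0.2)
    prof <- column_profiles(aln)
    m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
    ref <- m[1, ]
    hom <- m[-1, , drop = FALSE]
    cols <- which(ref != "-")
    for (i in seq_along(cols)) {
      for (aa in AA4) {
        expect_equal(prof[[paste0("n_", aa)]][i],
                     sum(hom[, cols[i]] == aa))
      }
    }
  })
})

test_that("single identical homolog gives wildtype frequency 1 everywhere", {
  aln <- msa_alignment(c("REF", "H1"), c("ACDEFGHIKL", "ACDEFGHIKL"), "REF")
  prof <- column_profiles(aln)
  calls <- call_consensus(prof, wt_max_freq = 1, consensus_min_freq = 0)
  expect_equal(nrow(calls), 0)  # modal residue is always the wildtype
  logo <- differential_logo_matrix(prof)
  expect_true(all(abs(as.matrix(logo[, -(1:2)])) < 1e-12))
})

test_that("consensus calling matches exhaustive enumeration on small MSAs", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      n_seq <- sample(2:6, 1)
      n_col <- sample(1:10, 1)
      aln <- random_small_msa(n_seq, n_col)
      thr <- list(wt = stats::runif(1, 0.1, 0.6),
                  cons = stats::runif(1, 0.3, 0.8),
                  cov = stats::runif(1, 0, 0.9))
      got <- call_consensus(column_profiles(aln), thr$wt, thr$cons, thr$cov)
      want <- oracle_consensus(aln, thr$wt, thr$cons, thr$cov)
      expect_equal(got[, c("ref_position", "wt_residue",
                           "proposed_residue")],
                   want, ignore_attr = TRUE)
    }
  })
})

test_that("threshold monotonicity holds for consensus calling", {
  withr::with_seed(7, {
    aln <- random_small_msa(6, 10)
    prof <- column_profiles(aln)
    for (wt_max in c(0.2, 0.4, 0.6)) {
      lo <- call_consensus(prof, wt_max_freq = wt_max,
                           consensus_min_freq = 0.4, min_coverage = 0)
      hi <- call_consensus(prof, wt_max_freq = wt_max + 0.2,
                           consensus_min_freq = 0.4, min_coverage = 0)
      expect_true(all(lo$ref_position %in% hi$ref_position))
    }
    for (cmin in c(0.3, 0.5)) {
      lo <- call_consensus(prof, 0.5, consensus_min_freq = cmin + 0.2,
                           min_coverage = 0)
      hi <- call_consensus(prof, 0.5, consensus_min_freq = cmin,
                           min_coverage = 0)
      expect_true(all(lo$ref_position %in% hi$ref_position))
    }
  })
})

test_that("planted signals at the ten stabilized sites are fully recovered", {
  g <- gen_msa(75, planted_calls = stable_sites())
  calls <- call_consensus(column_profiles(g$alignment))
  expect_equal(calls$ref_position, stable_sites()$position)
  expect_equal(calls$wt_residue, stable_sites()$wt)
  expect_equal(calls$proposed_residue, stable_sites()$consensus)
})

test_that("differential logo heights follow the frequency accounting", {
  ## planted column: wt A 1/5, K 3/5, R 1/5 over five homologs
  aln <- msa_alignment(c("REF", paste0("H", 1:5)),
                       c("A", "A", "K", "K", "K", "R"), "REF")
  prof <- column_profiles(aln)
  logo <- differential_logo_matrix(prof)
  expect_equal(logo$K, 3 / 5)
  expect_equal(logo$R, 1 / 5)
  expect_equal(logo$A, -(1 - 1 / 5))
  ## positive heights sum to 1 - wt frequency when no gaps
  pos_sum <- sum(pmax(as.numeric(logo[1, -(1:2)]), 0))
  expect_equal(pos_sum, 1 - 1 / 5)
  ## single call at default-ish thresholds
  calls <- call_consensus(prof, 0.3, 0.5, 0.5)
  expect_equal(calls$proposed_residue, "K")
})

test_that("modal ties break by count then alphabetical order", {
  aln <- msa_alignment(c("REF", paste0("H", 1:4)),
                       c("A", "K", "K", "R", "R"), "REF")
  calls <- call_consensus(column_profiles(aln), 0.3, 0.5, 0.5)
  expect_equal(calls$proposed_residue, "K")  # K before R
})

test_that("active-site exclusion removes calls by C-alpha distance", {
  ## three CA positions: active site at origin, calls at 7.9 and 8.1 A
  atoms <- data.frame(
    chain = "A", resno = c(1, 2, 3), resid = "ALA", elety = "CA",
    x = c(0, 7.9, 8.1), y = 0, z = 0, stringsAsFactors = FALSE)
  st <- pdb_structure(atoms)
  calls <- data.frame(ref_position = c(1, 2, 3), wt_residue = "A",
                      proposed_residue = "K", wt_frequency = 0.1,
                      consensus_frequency = 0.8, coverage = 1,
                      stringsAsFactors = FALSE)
  ## radius 0: unchanged
  expect_equal(nrow(exclude_near_active_site(calls, st, 1, 0)), 3)
  out <- exclude_near_active_site(calls, st, 1, 8)
  ## the active-site residue itself (d = 0) and the 7.9 A call are removed
  expect_equal(out$ref_position, 3)
  ## a call absent from the structure is retained and flagged
  calls2 <- rbind(calls, data.frame(ref_position = 99, wt_residue = "A",
                                    proposed_residue = "K",
                                    wt_frequency = 0.1,
                                    consensus_frequency = 0.8, coverage = 1))
  expect_warning(out2 <- exclude_near_active_site(calls2, st, 1, 8),
                 "absent")
  expect_true(99 %in% out2$ref_position)
  expect_true(out2$flagged_missing[out2$ref_position == 99])
})
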