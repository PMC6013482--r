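write_hdx_table <- function(rows) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("sequence,start,end,time_s,replicate,state,percent_D", rows), f)
  f
}

test_that("load_peptides validates records and groups replicates", {
  f <- write_hdx_table(c("ALKSGF,10,15,300,1,apo,42.0",
                         "ALKSGF,10,15,300,2,apo,43.5",
                         "ALKSGF,10,15,300,3,apo,41.0",
                         "BADLEN,10,20,300,1,apo,50.0",
                         "AG,15,10,300,1,apo,50.0",
                         "ALKSGF,10,15,300,1,apo,140.0"))
  peps <- load_peptides(f)
  expect_equal(nrow(peps), 3)
  rejects <- attr(peps, "rejects")
  expect_equal(nrow(rejects), 3)
  expect_setequal(rejects$reason,
                  c("sequence length does not match span", "end < start",
                    "deuteration outside [0, 110]"))
  expect_equal(length(unique(peps$replicate)), 3)
})

test_that("theoretical_max_sites counts exchangeable backbone amides", {
  expect_equal(theoretical_max_sites("AAAA"), 3)
  expect_equal(theoretical_max_sites("APAP"), 1)
  expect_equal(theoretical_max_sites("A"), 0)
  expect_equal(theoretical_max_sites("PAAA"), 3)  # position-1 P irrelevant
  expect_error(theoretical_max_sites("AZX9"), "non-amino-acid")
})

test_that("per-residue aggregation: prefix exclusion and unweighted means", {
  rec <- function(start, end, d, rep = 1) {
    data.frame(sequence = strrep("A", end - start + 1), start = start,
               end = end, time_s = 300, replicate = rep, state = "apo",
               percent_D = d)
  }
  # single peptide 10-20 at 40%, exclude 2: residues 12-20 covered at 40
  p <- per_residue_profile(rec(10, 20, 40), 300, exclude_prefix = 2)
  expect_equal(p$residue, 12:20)
  expect_true(all(p$mean_D == 40))
  # overlapping peptides at 50 and 70, exclude 0: shared residues = 60
  recs <- rbind(rec(10, 20, 50), rec(15, 25, 70))
  p2 <- per_residue_profile(recs, 300, exclude_prefix = 0)
  expect_true(all(p2$mean_D[p2$residue %in% 15:20] == 60))
  expect_true(all(p2$mean_D[p2$residue %in% 10:14] == 50))
  expect_true(all(p2$coverage[p2$residue %in% 15:20] == 2))
  # the stricter exclude-3 variant shifts the covered span
  p3 <- per_residue_profile(rec(10, 20, 40), 300, exclude_prefix = 3)
  expect_equal(min(p3$residue), 13)
  # mean always within range of contributing peptide values
  expect_true(all(p2$mean_D >= 50 & p2$mean_D <= 70))
})

test_that("SEM is computed across replicates, not peptides", {
  rec3 <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(sequence = strrep("A", 6), start = 1, end = 6, time_s = 300,
               replicate = r, state = "apo", percent_D = c(40, 50, 60)[r])
  }))
  p <- per_residue_profile(rec3, 300)
  expect_true(all(p$mean_D == 50))
  expect_equal(unique(p$sem_D), stats::sd(c(40, 50, 60)) / sqrt(3))
  # single replicate: SEM undefined
  p1 <- per_residue_profile(rec3[1, ], 300)
  expect_true(all(is.na(p1$sem_D)))
})

test_that("aggregation equals a brute-force per-residue oracle on random tilings", {
  for (seed in 1:5) {
    set.seed(seed)
    n_pep <- 12
    starts <- sample(1:60, n_pep)
    lens <- sample(5:12, n_pep, replace = TRUE)
    recs <- data.frame(sequence = strrep("A", lens), start = starts,
                       end = starts + lens - 1, time_s = 300, replicate = 1,
                       state = "apo",
                       percent_D = round(stats::runif(n_pep, 10, 90), 2))
    ex <- sample(0:3, 1)
    p <- per_residue_profile(recs, 300, exclude_prefix = ex)
    # oracle: direct accumulation loop
    acc <- list()
    for (i in seq_len(n_pep)) {
      span <- (recs$start[i] + ex):recs$end[i]
      span <- span[span >= recs$start[i]]
      for (r in span)
        acc[[as.character(r)]] <- c(acc[[as.character(r)]], recs$percent_D[i])
    }
    for (r in p$residue) {
      expect_equal(p$mean_D[p$residue == r],
                   mean(acc[[as.character(r)]]))
      expect_equal(p$coverage[p$residue == r],
                   length(acc[[as.character(r)]]))
    }
    expect_setequal(as.character(p$residue), names(acc))
  }
})

test_that("differential profiles are antisymmetric and coverage-limited", {
  rec <- function(start, end, d, state) {
    data.frame(sequence = strrep("A", end - start + 1), start = start,
               end = end, time_s = 300, replicate = 1, state = state,
               percent_D = d)
  }
  recs <- rbind(rec(1, 50, 30, "plus"), rec(40, 90, 80, "minus"))
  pa <- per_residue_profile(recs, 300, exclude_prefix = 0, state = "plus")
  pb <- per_residue_profile(recs, 300, exclude_prefix = 0, state = "minus")
  d1 <- differential(pa, pb)
  expect_equal(range(d1$residue), c(40, 50))
  expect_true(all(d1$delta_D == -50))
  d2 <- differential(pb, pa)
  expect_equal(d2$delta_D, -d1$delta_D)
  expect_true(all(abs(d1$delta_D) <= 100 + 1e-9))
  # A = B gives the all-zero profile
  expect_true(all(differential(pa, pa)$delta_D == 0))
  # disjoint coverage warns
  pc <- per_residue_profile(rec(60, 90, 10, "plus"), 300,
                            exclude_prefix = 0)
  expect_warning(differential(pa, pc), "disjoint")
})
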