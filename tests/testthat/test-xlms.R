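write_xl_table <- function(rows) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("residueA,residueB,linker,score,count", rows), f)
  f
}

test_that("parse_crosslinks enforces residue chemistry per linker", {
  f <- write_xl_table(c("K157,K157,DSS,120,4",
                        "E111,K255,DMTMM,95,2",
                        "G12,K50,DMTMM,80,1",
                        "K173,S305,BS3,70,3",
                        "xx,K50,DSS,10,1"))
  links <- parse_crosslinks(f)
  expect_equal(nrow(links), 3)
  expect_equal(links$resA, c(157, 111, 173))
  rejects <- attr(links, "rejects")
  expect_equal(nrow(rejects), 2)
  expect_match(rejects$reason[1], "DMTMM chemistry")
  expect_match(rejects$reason[2], "malformed")
  expect_error(parse_crosslinks(write_xl_table("K1,K2,EDC,5,1")),
               "unknown linker")
})

test_that("map_distances: inclusive bounds and linker-specific limits", {
  m <- calpha_model(rbind(c(0, 0, 0), c(29.9, 0, 0), c(100, 0, 0)),
                    resno = c(157, 300, 400))
  link <- function(linker) data.frame(resA = 157, aaA = "K", resB = 300,
                                      aaB = "E", linker = linker,
                                      score = NA, count = NA)
  expect_true(map_distances(link("DMTMM"), m)$satisfied)   # 29.9 <= 30
  expect_true(map_distances(link("DSS"), m)$satisfied)     # 29.9 <= 35
  far <- data.frame(resA = 157, aaA = "K", resB = 400, aaB = "E",
                    linker = "DMTMM", score = NA, count = NA)
  expect_false(map_distances(far, m)$satisfied)
  # boundary is inclusive at exactly the bound
  m30 <- calpha_model(rbind(c(0, 0, 0), c(30, 0, 0)), resno = c(157, 300))
  expect_true(map_distances(link("DMTMM"), m30)$satisfied)
})

test_that("homotypic links on a C4 assembly match the exhaustive-assignment oracle", {
  prot <- make_helix_bundle(40, seed = 6)
  asm <- assemble_c4(prot, list(angles = c(0.5, 0.4, 0.1), rho = 22))
  links <- data.frame(resA = c(5, 20, 33), aaA = "K",
                      resB = c(5, 20, 33), aaB = "K",
                      linker = "DSS", score = NA, count = NA)
  rep_ <- map_distances(links, asm)
  for (i in 1:3) {
    r <- links$resA[i]
    k <- match(r, prot$resno)
    oracle <- min(vapply(utils::combn(4, 2, simplify = FALSE), function(p) {
      sqrt(sum((asm[[p[1]]]$xyz[k, ] - asm[[p[2]]]$xyz[k, ])^2))
    }, 0))
    expect_equal(rep_$distance[i], oracle, tolerance = 1e-9)
    expect_false(rep_$assignment[i] == "intra")
  }
  # unresolvable residue produces a per-link error, not a global failure
  bad <- rbind(links, data.frame(resA = 999, aaA = "K", resB = 5, aaB = "K",
                                 linker = "DSS", score = NA, count = NA))
  rep2 <- map_distances(bad, asm)
  expect_false(is.na(rep2$error[4]))
  expect_true(all(is.na(rep2$error[1:3])))
})

test_that("single-protomer mapping equals the naive pairwise distance", {
  m <- make_helix_bundle(30, seed = 2)
  links <- data.frame(resA = c(1, 5, 10), aaA = "K", resB = c(20, 25, 30),
                      aaB = "E", linker = "DMTMM", score = NA, count = NA)
  rep_ <- map_distances(links, m)
  for (i in 1:3) {
    d <- sqrt(sum((m$xyz[links$resA[i], ] - m$xyz[links$resB[i], ])^2))
    expect_equal(rep_$distance[i], d)
    expect_equal(rep_$assignment[i], "intra")
  }
})

test_that("reported distances are invariant under rigid transforms of the assembly", {
  prot <- make_helix_bundle(30, seed = 8)
  asm <- assemble_c4(prot, list(angles = c(0.2, 0.1, 0), rho = 20))
  links <- data.frame(resA = c(3, 12), aaA = "K", resB = c(3, 25),
                      aaB = c("K", "E"), linker = c("DSS", "DMTMM"),
                      score = NA, count = NA)
  d0 <- map_distances(links, asm)$distance
  R <- tetraconf:::euler_zyz(1.1, 0.6, -0.3)
  asm2 <- lapply(asm, tetraconf:::transform_model, rotation = R,
                 translation = c(12, -7, 4))
  expect_equal(map_distances(links, asm2)$distance, d0, tolerance = 1e-6)
})

test_that("classify_intersubunit: homotypic links are the unambiguous ones", {
  links <- data.frame(resA = c(157, 173), aaA = "K", resB = c(157, 305),
                      aaB = "K", linker = "DSS", score = NA, count = NA)
  part <- classify_intersubunit(links)
  expect_equal(part$unambiguous_inter$resA, 157)
  expect_equal(part$ambiguous$resA, 173)
  empty <- classify_intersubunit(links[0, ])
  expect_equal(nrow(empty$unambiguous_inter), 0)
  expect_equal(nrow(empty$ambiguous), 0)
})

test_that("satisfaction_score handles weights and stays monotone in the bound", {
  m <- calpha_model(rbind(c(0, 0, 0), c(10, 0, 0), c(50, 0, 0),
                          c(80, 0, 0)),
                    resno = c(1, 2, 3, 4))
  links <- data.frame(resA = c(1, 1, 1, 2), aaA = "K",
                      resB = c(2, 3, 4, 3), aaB = "E",
                      linker = "DMTMM", score = NA, count = NA)
  rep_ <- map_distances(links, m)  # distances 10, 50, 80, 40
  expect_equal(satisfaction_score(rep_), 0.25)
  # weighted case: weights 1,1,2 with the middle link violated -> 0.75
  rep3 <- map_distances(links[c(1, 2, 1), ], m)
  expect_equal(satisfaction_score(rep3, weights = c(1, 1, 2)), 0.75)
  expect_error(satisfaction_score(rep_[0, ]), "empty report")
  # increasing any bound never decreases the score
  score_with <- function(b) satisfaction_score(
    map_distances(links, m, bounds = c(DMTMM = b, DSS = 35, BS3 = 35)))
  scores <- vapply(c(5, 15, 45, 60, 90), score_with, 0)
  expect_true(all(diff(scores) >= 0))
})
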