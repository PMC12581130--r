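make_two_frame_traj <- function(gap1, gap2) {
  ## two 2-residue chains; inter-chain gap differs per frame
  ch <- build_glutamine_chain(2, data.frame(phi = -139, psi = 135,
                                            chi1 = -60, chi2 = 180))
  tops <- list(ch$topology, chain_topology("B", ch$topology$atoms))
  mk <- function(gap, t) new_frame(rbind(ch$coords,
                                         sweep(ch$coords, 2, c(0, gap, 0), "+")),
                                   time = t)
  trajectory(tops, list(mk(gap1, 0), mk(gap2, 1)))
}

test_that("contact probability is the fraction of frames in contact", {
  tr <- make_two_frame_traj(5, 40)
  cm <- extract_contacts(tr, "INTER", cutoff = 6, source = "DENSE")
  expect_true(all(cm$probability == 0.5))
  expect_equal(attr(cm, "scope"), "INTER")
  expect_equal(attr(cm, "source"), "DENSE")
})

test_that("INTRA maps exclude pairs below the minimum sequence separation", {
  ch <- build_glutamine_chain(6, data.frame(phi = -139, psi = 135,
                                            chi1 = -60, chi2 = 180))
  tr <- trajectory(list(ch$topology), list(new_frame(ch$coords)))
  cm <- extract_contacts(tr, "INTRA", cutoff = 8, min_seq_sep = 2)
  expect_true(all(abs(cm$i - cm$j) >= 2))
  cm3 <- extract_contacts(tr, "INTRA", cutoff = 8, min_seq_sep = 3)
  expect_true(all(abs(cm3$i - cm3$j) >= 3))
  expect_error(extract_contacts(trajectory(list(ch$topology), list()),
                                "INTRA"), "empty|non-decreasing|frame")
})

test_that("INTER map on an ideal lattice matches the brute-force scan", {
  lat <- build_lattice(lattice_spec("BT", "A1", 2, 2))
  tr <- trajectory(lat$topologies, list(lat$frame))
  cm <- extract_contacts(tr, "INTER", cutoff = 6, source = "FIBRIL")
  expect_gt(nrow(cm), 0)
  tab <- atom_table(lat$topologies)
  oracle <- contact_oracle(tab, lat$frame$coords, lat$frame, 6, "INTER")
  for (k in seq_len(nrow(cm))) {
    expect_equal(cm$probability[k], oracle[as.character(cm$i[k]),
                                           as.character(cm$j[k])])
  }
})

h16_topology <- function() {
  assign_domains(
    chain_topology("A", data.frame(
      residue_index = rep(1:38, each = 2), residue_name = "GLN",
      atom_name = rep(c("N", "CA"), 38), element = rep(c("N", "C"), 38))),
    list(N17 = c(1, 17), QCORE = c(18, 33), P5 = c(34, 38)))
}

fake_map <- function(pairs, prob = 1) {
  structure(data.frame(i = pairs[, 1], j = pairs[, 2], probability = prob),
            class = c("contact_map", "data.frame"))
}

test_that("multi-state merge enforces the excluded-volume and epsilon rules", {
  top <- h16_topology()
  fib <- fake_map(cbind(20, c(24, 25, 26)))
  mono <- fake_map(cbind(19, 23), 0.5)
  dense <- fake_map(rbind(c(2, 8), c(35, 37), c(5, 36)))
  p <- merge_multistate(mono, fib, dense, top, epsilon = 0.325)
  pick <- function(i, j) p[p$i == min(i, j) & p$j == max(i, j), ]
  ## flanking-QCORE cross pairs are excluded volume, whatever the maps say
  expect_equal(pick(5, 20)$kind, "REPULSIVE")
  expect_equal(pick(36, 20)$kind, "REPULSIVE")
  expect_true(all(p$kind[p$provenance == "excluded_volume"] == "REPULSIVE"))
  ## QCORE native contacts: fibril provenance, configured epsilon
  expect_equal(pick(20, 24)$kind, "ATTRACTIVE")
  expect_equal(pick(20, 24)$provenance, "fibril")
  expect_equal(pick(19, 23)$provenance, "monomer")
  expect_true(all(p$epsilon[p$kind == "ATTRACTIVE"] == 0.325))
  ## flanking-flanking from the dense map
  expect_equal(pick(2, 8)$kind, "ATTRACTIVE")
  expect_equal(pick(2, 8)$provenance, "dense")
  expect_equal(pick(35, 37)$provenance, "dense")
  ## table covers every unordered pair exactly once
  expect_equal(nrow(p), choose(38, 2))
  expect_true(all(p$i < p$j))
})

test_that("merge validates inputs and handles degenerate maps", {
  top <- h16_topology()
  expect_error(merge_multistate(NULL, NULL, NULL, top, 0.325), "dense")
  bad <- fake_map(cbind(50, 60))
  expect_error(merge_multistate(bad, NULL, fake_map(cbind(2, 8)), top, 0.325),
               "collide")
  ## Q16 topology: no flanking domains, dense map optional; eps carried
  q16 <- assign_domains(
    chain_topology("A", data.frame(
      residue_index = rep(1:16, each = 2), residue_name = "GLN",
      atom_name = rep(c("N", "CA"), 16), element = rep(c("N", "C"), 16))),
    list(QCORE = c(1, 16)))
  p <- merge_multistate(fake_map(cbind(2, 9)), NULL, NULL, q16, 0.4)
  expect_true(all(p$epsilon[p$kind == "ATTRACTIVE"] == 0.4))
  expect_equal(sum(p$provenance == "fibril"), 0L)
  expect_true(nrow(p) == choose(16, 2))
})

test_that("raising the inclusion threshold never adds attractive entries", {
  top <- h16_topology()
  set.seed(30)
  pr <- cbind(sample(18:33, 20, TRUE), sample(18:33, 20, TRUE))
  pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
  m <- fake_map(pr, runif(nrow(pr)))
  dense <- fake_map(cbind(2, 8), 0.9)
  prev <- Inf
  for (thr in c(0.01, 0.1, 0.3, 0.7)) {
    p <- merge_multistate(m, m, dense, top, 0.325, threshold = thr)
    n_att <- sum(p$kind == "ATTRACTIVE")
    expect_lte(n_att, prev)
    prev <- n_att
  }
})

test_that("parameter tables round-trip through TSV", {
  top <- h16_topology()
  p <- merge_multistate(fake_map(cbind(19, 23)), fake_map(cbind(20, 24)),
                        fake_map(cbind(2, 8)), top, 0.325)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  ## duplicate pair detection
  dup <- rbind(as.data.frame(p)[1:2, ], as.data.frame(p)[1, ])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(dup, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_params(f2), "duplicate")
  ## unknown kind token
  bad <- as.data.frame(p)[1:2, ]
  bad$kind <- "STICKY"
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_params(f3), "kind")
  ## empty table: header-only file is valid
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_params(p[0, ], f4)
  expect_equal(nrow(read_params(f4)), 0L)
})
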