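test_that("align_sequences: identity values against hand-built DP cases", {
  expect_equal(align_sequences("ACDEFGHIKL", "ACDEFGHIKL", cfg)$identity_pct,
               100)
  expect_equal(align_sequences("ACDEFG", "ACDEFN", cfg)$identity_pct,
               100 * 5 / 6)
  # one internal deletion in a 10-aa pair: hand DP gives the obvious
  # alignment ACDEFGHIKL / ACDE-GHIKL -> 9 identical / 10 columns
  aln <- align_sequences("ACDEFGHIKL", "ACDEGHIKL", cfg)
  expect_equal(aln$identity_pct, 90)
  expect_equal(nchar(aln$aligned1), 10)
  expect_error(align_sequences("", "ACD"), "empty")
})

test_that("pair_residues maps alignment columns to residue indices", {
  fx <- make_synthetic_chain(8, seed = 1)
  ch <- fx$model$chains$A
  pr <- pair_residues(ch, ch)
  expect_equal(pr$i, 1:8)
  expect_equal(pr$j, 1:8)
  expect_false(any(pr$type_mismatch))
  # gap column produces no pair; mutation column is flagged
  chB <- ch[-4]  # delete residue 4
  prB <- pair_residues(ch, chB)
  expect_equal(nrow(prB), 7)
  expect_false(4 %in% prB$i[!prB$type_mismatch & prB$j == prB$i])
})

test_that("curate_pair enforces every criterion with named reasons", {
  fx <- make_synthetic_chain(120, seed = 2, pdb_id = "2vb1")
  vp <- make_variant_pair(fx, 0.1, seed = 3, pdb_id = "1iee")
  mA <- fx$model; mB <- vp$model
  # cross-crystal: "2vb1" vs "1iee" differ in 4 of 4 characters -> eligible
  cur <- curate_pair(mA, mB, "A", "A", mode = "cross-crystal", config = cfg)
  expect_true(cur$accept)
  expect_gt(cur$superposition$tm_score, 0.8)
  expect_lt(cur$superposition$rmsd, 3.0)
  # id distance <= 2 rejected in cross-crystal mode ("more than two letters
  # different": 2pa8/2pmz differ at exactly two positions)
  mB2 <- mB; mB2$pdb_id <- "2pmz"
  mA2 <- mA; mA2$pdb_id <- "2pa8"
  expect_true("pdb-id" %in%
    curate_pair(mA2, mB2, "A", "A", mode = "cross-crystal", config = cfg)$reasons)
  # same-crystal mode needs one entry, two chains
  mAB <- mA; mAB$chains$B <- mB$chains$A
  expect_true(curate_pair(mAB, mAB, "A", "B", mode = "same-crystal",
                          config = cfg)$accept)
  expect_true("pdb-id" %in% curate_pair(mA, mB, "A", "A",
                                        mode = "same-crystal",
                                        config = cfg)$reasons)
  # resolution filter and missing resolution
  mBad <- mA; mBad$resolution <- 3.9
  expect_true("resolution" %in%
    curate_pair(mBad, mB, mode = "cross-crystal", config = cfg)$reasons)
  mNA <- mA; mNA$resolution <- NA_real_
  expect_true("resolution-missing" %in%
    curate_pair(mNA, mB, mode = "cross-crystal", config = cfg)$reasons)
  expect_false(curate_pair(mNA, mB, mode = "cross-crystal",
                           config = cfg)$accept)
  # length filter (>100 aa)
  sh <- make_synthetic_chain(50, seed = 5, pdb_id = "1abc")
  shB <- make_variant_pair(sh, 0, seed = 6, pdb_id = "9xyz")
  expect_true("length" %in%
    curate_pair(sh$model, shB$model, mode = "cross-crystal",
                config = cfg)$reasons)
  # TM filter: second half of the chain displaced far away
  mSplit <- mB
  for (i in 61:120) {
    a <- mSplit$chains$A[[i]]$atoms
    a$x <- a$x + 40; a$y <- a$y - 25
    mSplit$chains$A[[i]]$atoms <- a
  }
  curT <- curate_pair(mA, mSplit, "A", "A", mode = "cross-crystal",
                      config = cfg)
  expect_true(any(c("tm", "rmsd") %in% curT$reasons))
})

test_that("altloc_variation aggregates over all state pairs", {
  fx <- make_synthetic_chain(6, rep("LYS", 6), seed = 7)
  # small wiggle: same_all
  m1 <- inject_altlocs(fx$model, "A:2", list(c(2, 0, 0, 0)), c(0.5, 0.5))
  r <- altloc_variation(m1$chains$A[[2]], cfg)
  expect_true(r$keeps_all); expect_false(r$changed)
  # chi1 rotation: changed at chi1
  m2 <- inject_altlocs(fx$model, "A:2", list(c(120, 0, 0, 0)), c(0.5, 0.5))
  r2 <- altloc_variation(m2$chains$A[[2]], cfg)
  expect_false(r2$keeps_chi1); expect_true(r2$changed)
  # 3 states, one deviant pair -> residue changed
  m3 <- inject_altlocs(fx$model, "A:2",
                       list(c(1, 0, 0, 0), c(100, 0, 0, 0)),
                       c(0.4, 0.3, 0.3))
  r3 <- altloc_variation(m3$chains$A[[2]], cfg)
  expect_equal(r3$n_states, 3)
  expect_true(r3$changed)
  # single-state residue yields no record
  expect_null(altloc_variation(fx$model$chains$A[[1]], cfg))
  # 20 states at occupancy 0.05 each are all recovered
  m20 <- inject_altlocs(fx$model, "A:3",
                        lapply(1:19, function(k) c(k * 7, 0, 0, 0)),
                        rep(0.05, 20))
  expect_length(group_conformers(read_pdb(write_pdb(m20))$chains$A[[3]]), 20)
})

test_that("pair_variation recovers injected changes and applies exclusions", {
  fx <- make_synthetic_chain(50, seed = 11)
  vp <- make_variant_pair(fx, 0.2, seed = 12)
  recs <- pair_variation(fx$model$chains$A, vp$model$chains$A, config = cfg)
  expect_equal(sum(recs$changed), sum(vp$truth$changed))
  expect_equal(sort(recs$seq_id[recs$changed]),
               sort(as.character(which(vp$truth$changed))))
  # identical chains: all same_all
  recs0 <- pair_variation(fx$model$chains$A, fx$model$chains$A, config = cfg)
  expect_true(all(recs0$same_all))
  expect_true(all(recs0$delta_chi1 < 1e-9))
  # chi same but backbone changed: same_all with backbone_changed
  bbB <- make_synthetic_chain(10, rep("LEU", 10),
                              chi_assignments = rep(list(c(-60, 170)), 10),
                              seed = 13)
  bb2 <- scvar:::build_backbone(10, phi = -100, psi = -47)
  modB <- bbB$model
  for (i in 1:10) {
    st <- build_sidechain("LEU", c(-60, 170),
                          list(N = bb2$N[i, ], CA = bb2$CA[i, ],
                               C = bb2$C[i, ]))
    o_at <- scvar:::new_atom_table("O", "O", bb2$O[i, 1], bb2$O[i, 2],
                                   bb2$O[i, 3], "", 1, 20, FALSE)
    modB$chains$A[[i]] <- scvar:::residue_from_state(st, o_at, i, "A", "LEU")
  }
  recsb <- pair_variation(bbB$model$chains$A, modB$chains$A, config = cfg)
  interior <- recsb[!is.na(recsb$backbone_changed), ]
  expect_true(all(interior$same_all))
  expect_true(all(interior$backbone_changed))
  # altloc residues excluded
  mAlt <- inject_altlocs(fx$model, "A:5", list(c(120, 0, 0, 0)), c(0.5, 0.5))
  recsA <- pair_variation(mAlt$chains$A, vp$model$chains$A, config = cfg)
  expect_false("5" %in% recsA$seq_id)
  # reliability-FALSE residues excluded
  relA <- rep(TRUE, 50); relA[10] <- FALSE
  recsR <- pair_variation(fx$model$chains$A, vp$model$chains$A, config = cfg,
                          reliableA = relA)
  expect_false("10" %in% recsR$seq_id)
})

test_that("excluding altloc residues never raises the changed percentage when
           injected changes sit in excluded residues", {
  fx <- make_synthetic_chain(40, seed = 21)
  vp <- make_variant_pair(fx, 0.25, seed = 22)
  changed_keys <- paste0("A:", which(vp$truth$changed))
  # give every changed residue an altloc in chain A -> excluded from survey
  mAlt <- fx$model
  for (k in changed_keys)
    mAlt <- inject_altlocs(mAlt, k, list(c(1, 0, 0, 0)), c(0.5, 0.5))
  recs <- pair_variation(mAlt$chains$A, vp$model$chains$A, config = cfg)
  expect_equal(sum(recs$changed), 0)
})

test_that("aggregate_survey averages per structure first", {
  mk <- function(id, res, n_same, n_changed) {
    data.frame(structure_id = id, resolution = res,
               res_name = "LYS", exposedA = TRUE,
               same_chi1 = c(rep(TRUE, n_same), rep(FALSE, n_changed)),
               same_chi12 = c(rep(TRUE, n_same), rep(FALSE, n_changed)),
               same_all = c(rep(TRUE, n_same), rep(FALSE, n_changed)),
               changed = c(rep(FALSE, n_same), rep(TRUE, n_changed)))
  }
  # two structures in one bin: 80% and 90% same -> mean 85, population SD 5
  recs <- rbind(mk("s1", 1.5, 8, 2), mk("s2", 1.5, 9, 1))
  tbl <- aggregate_survey(recs, "resolution", cfg)
  expect_equal(tbl$group, "1.0-2.0")
  expect_equal(tbl$pct_same_all, 85)
  expect_equal(tbl$sd_same_all, 5)
  expect_equal(tbl$n_structures, 2)
  # per-structure-first differs from pooling on unbalanced cohorts:
  # s1 50 records 100%, s2 2 records 0% -> mean 50, pooled would be 96
  recs2 <- rbind(mk("s1", 0.9, 50, 0), mk("s2", 0.9, 0, 2))
  tbl2 <- aggregate_survey(recs2, "resolution", cfg)
  expect_equal(tbl2$pct_same_all, 50)
  expect_equal(tbl2$group, "<1.0")
  # permutation invariance
  perm <- recs[sample(nrow(recs)), ]
  expect_equal(aggregate_survey(perm, "resolution", cfg)$pct_same_all, 85)
  # sample SD config switch
  tbl_s <- aggregate_survey(recs, "resolution",
                            scvar_config(sd_type = "sample"))
  expect_equal(tbl_s$sd_same_all, sd(c(80, 90)))
  # monotone category percentages in every row
  fx <- make_synthetic_chain(30, seed = 31)
  vp <- make_variant_pair(fx, 0.3, seed = 32)
  r <- pair_variation(fx$model$chains$A, vp$model$chains$A, config = cfg)
  r$structure_id <- "x"; r$resolution <- 1.2
  t3 <- aggregate_survey(r, "res_name", cfg)
  expect_true(all(t3$pct_same_all <= t3$pct_same_chi12 + 1e-9))
  expect_true(all(t3$pct_same_chi12 <= t3$pct_same_chi1 + 1e-9))
})

test_that("flexibility_estimate reproduces the published arithmetic", {
  expect_equal(flexibility_estimate(12, 95), 17)
  expect_equal(flexibility_estimate(3, 87), 16)
  expect_equal(flexibility_estimate(12, 95, 3), 20)
  expect_error(flexibility_estimate(-1, 50), "0, 100")
  expect_error(flexibility_estimate(12, 101), "0, 100")
})
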