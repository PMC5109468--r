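test_that("build_ensemble collects every altloc state from every source", {
  fx <- make_synthetic_chain(12, seed = 41)
  ens1 <- build_ensemble(list(fx$model))
  expect_true(all(vapply(ens1$entries, function(e)
    length(e$conformers) == 1, logical(1))))
  # altloc states both included, never only 'A'
  mAlt <- inject_altlocs(fx$model, "A:4", list(c(120, 0, 0, 0)), c(0.45, 0.55))
  ens2 <- build_ensemble(list(mAlt))
  expect_length(ens2$entries[[4]]$conformers, 2)
  # second crystal with divergent rotamers adds conformers
  vp <- make_variant_pair(fx, 0.5, seed = 42, pdb_id = "othr")
  ens3 <- build_ensemble(list(fx$model, vp$model))
  expect_true(all(vapply(ens3$entries, function(e)
    length(e$conformers) == 2, logical(1))))
  expect_error(build_ensemble(list()), "no native")
})

test_that("closest_conformer minimizes the max chi difference with tie rules", {
  entry <- list(res_name = "SER", seq_id = "1", conformers = list(
    list(chis = 60, provenance = "a:A:1", state_id = "A", reliable = NA),
    list(chis = 180, provenance = "a:A:1", state_id = "B", reliable = NA)))
  cc <- closest_conformer(58, entry, cfg)
  expect_equal(cc$index, 1)
  expect_equal(cc$deltas[1], 2)
  # exact match to state B
  cc2 <- closest_conformer(180, entry, cfg)
  expect_equal(cc2$index, 2)
  expect_equal(cc2$deltas[1], 0)
  # tie on the max: broken by smaller chi1 difference
  entry2 <- list(res_name = "LEU", seq_id = "1", conformers = list(
    list(chis = c(60, 100), provenance = "p1", state_id = "A", reliable = NA),
    list(chis = c(75, 85), provenance = "p2", state_id = "B", reliable = NA)))
  # prediction (70, 85): deltas A = (10, 15), B = (5, 0) -> B wins on max
  ccB <- closest_conformer(c(70, 85), entry2, cfg)
  expect_equal(ccB$index, 2)
  # prediction (65, 95): A = (5, 5) max 5; B = (10, 10) max 10 -> A
  ccA <- closest_conformer(c(65, 95), entry2, cfg)
  expect_equal(ccA$index, 1)
  # constructed tie: A = (15, 5) max 15, B = (5, 15) max 15 -> chi1 rule -> B
  entry3 <- list(res_name = "LEU", seq_id = "1", conformers = list(
    list(chis = c(60, 100), provenance = "p1", state_id = "A", reliable = NA),
    list(chis = c(70, 110), provenance = "p2", state_id = "B", reliable = NA)))
  cct <- closest_conformer(c(75, 95), entry3, cfg)
  expect_equal(cct$index, 2)
  expect_null(closest_conformer(60, list(res_name = "SER", conformers = list()),
                                cfg))
})

test_that("chi_accuracy: perfect prediction, constructed errors, monotonicity", {
  fx <- make_synthetic_chain(40, seed = 43)
  ens <- build_ensemble(list(fx$model))
  perfect <- chi_accuracy(fx$model, ens, cfg)
  expect_equal(perfect$chi1_pct, 100)
  expect_equal(perfect$chi12_pct, 100)
  expect_equal(perfect$chi_all_pct, 100)
  expect_equal(perfect$n_assessed, 40)
  # 10 of 40 residues off by 120 degrees at chi1 -> chi1 = 75%
  vp <- make_variant_pair(fx, 0.25, seed = 44)
  expect_equal(sum(vp$truth$changed), 10)
  rep10 <- chi_accuracy(vp$model, ens, cfg)
  expect_equal(rep10$chi1_pct, 75)
  expect_lte(rep10$chi_all_pct, rep10$chi12_pct)
  expect_lte(rep10$chi12_pct, rep10$chi1_pct)
})

test_that("ensemble scoring dominates single-native scoring (exhaustive)", {
  fx <- make_synthetic_chain(25, seed = 45)
  vp <- make_variant_pair(fx, 0.4, seed = 46, pdb_id = "othr")
  natives <- list(fx$model, vp$model)
  # predictions matching one native, the other, and a mixture
  mix <- make_variant_pair(fx, 0.2, seed = 47, pdb_id = "pred")
  for (pred in list(fx$model, vp$model, mix$model)) {
    acc_ens <- chi_accuracy(pred, build_ensemble(natives), cfg)
    for (single in natives) {
      acc_one <- chi_accuracy(pred, build_ensemble(list(single)), cfg)
      expect_gte(acc_ens$chi1_pct, acc_one$chi1_pct)
      expect_gte(acc_ens$chi12_pct, acc_one$chi12_pct)
      expect_gte(acc_ens$chi_all_pct, acc_one$chi_all_pct)
    }
  }
})

test_that("prediction matching state 'B' scores 100% where 'A'-only scores 0%", {
  fx <- make_synthetic_chain(20, seed = 48)
  deviant <- c("A:3", "A:7", "A:15")
  mAlt <- fx$model
  for (k in deviant)
    mAlt <- inject_altlocs(mAlt, k, list(c(120, 0, 0, 0)), c(0.5, 0.5))
  # prediction adopts the B state at the deviant residues
  pred <- fx$model
  for (k in c(3, 7, 15)) {
    res <- mAlt$chains$A[[k]]
    stB <- group_conformers(res)[[2]]
    ds <- measure_chis(stB, res$res_name)
    frame <- list(N = scvar:::atom_xyz(res$atoms, "N"),
                  CA = scvar:::atom_xyz(res$atoms, "CA"),
                  C = scvar:::atom_xyz(res$atoms, "C"))
    st <- build_sidechain(res$res_name, ds$chis, frame)
    o_row <- res$atoms[res$atoms$name == "O" & res$atoms$altloc == "", ,
                       drop = FALSE]
    pred$chains$A[[k]] <- scvar:::residue_from_state(st, o_row, res$number,
                                                     "A", res$res_name)
  }
  full <- chi_accuracy(pred, build_ensemble(list(mAlt)), cfg)
  expect_equal(full$chi_all_pct, 100)
  # naive contrast oracle: ensemble restricted to first ('A') states only
  naive_ens <- build_ensemble(list(mAlt))
  for (i in seq_along(naive_ens$entries))
    naive_ens$entries[[i]]$conformers <- naive_ens$entries[[i]]$conformers[1]
  naive <- chi_accuracy(pred, naive_ens, cfg)
  dev_rows <- naive$detail[naive$detail$seq_id %in% c("3", "7", "15"), ]
  expect_equal(sum(dev_rows$chi1_ok), 0)
  expect_equal(naive$n_assessed - sum(naive$detail$chi1_ok), 3)
})

test_that("unreliable-in-all-sources residues are excluded when a map is given", {
  fx <- make_synthetic_chain(10, seed = 49)
  map <- render_density(fx$model, seed = 1)
  # zero out density around residue 5's side chain -> unreliable there
  res5 <- fx$model$chains$A[[5]]
  sc <- scvar:::heavy_atoms(res5$atoms)
  sc <- sc[sc$is_sidechain, ]
  g <- map$grid
  spacing <- 0.5
  for (i in seq_len(nrow(sc))) {
    idx <- round(as.numeric(sc[i, c("x", "y", "z")]) / spacing) - map$start + 1
    lo <- pmax(idx - 4, 1); hi <- pmin(idx + 4, dim(g))
    g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- -1
  }
  map$grid <- g
  ens <- build_ensemble(list(fx$model), maps = list(map), config = cfg)
  expect_true(ens$entries[[5]]$excluded_unreliable)
  acc <- chi_accuracy(fx$model, ens, cfg)
  expect_equal(acc$n_excluded, 1)
  expect_equal(acc$n_assessed, 9)
  # filter-independence: remaining residues all still correct
  expect_equal(acc$chi1_pct, 100)
})

test_that("density_sum_score: node arithmetic, additivity, displacement", {
  # 3 atoms on nodes of values 1, 2, 3 sigma -> 6.0
  g <- array(0, dim = c(7, 3, 3))
  g[1, 1, 1] <- 1; g[3, 1, 1] <- 2; g[5, 1, 1] <- 3
  m <- fabricated_map(g, spacing = 1)
  at <- rbind(atom_at(0, 0, 0, "CB"), atom_at(2, 0, 0, "CG"),
              atom_at(4, 0, 0, "CD"))
  pm <- residue_model(at, res_name = "LYS")
  ds <- density_sum_score(pm, m, cfg)
  expect_equal(ds$total, 6.0)
  # additive over disjoint residue sets
  fx <- make_synthetic_chain(8, seed = 50)
  map <- render_density(fx$model, seed = 2)
  whole <- density_sum_score(fx$model, map, cfg)
  part1 <- fx$model; part1$chains$A <- part1$chains$A[1:4]
  part2 <- fx$model; part2$chains$A <- part2$chains$A[5:8]
  s1 <- density_sum_score(part1, map, cfg)$total
  s2 <- density_sum_score(part2, map, cfg)$total
  expect_equal(whole$total, s1 + s2, tolerance = 1e-9)
  # empty prediction scores 0 with warning
  gly <- residue_model(rbind(atom_at(0, 0, 0, "N", "N"),
                             atom_at(1.5, 0, 0, "CA")), res_name = "GLY")
  expect_warning(z <- density_sum_score(gly, m, cfg), "0")
  expect_equal(z$total, 0)
})

test_that("native model outscores a 2 A displaced copy on >= 95% of seeds", {
  fx <- make_synthetic_chain(10, seed = 51)
  map <- render_density(fx$model, seed = 3)
  native_score <- density_sum_score(fx$model, map, cfg)$total
  wins <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    disp <- fx$model
    for (i in seq_along(disp$chains$A)) {
      dirn <- rnorm(3); dirn <- dirn / sqrt(sum(dirn^2)) * 2
      a <- disp$chains$A[[i]]$atoms
      sel <- a$is_sidechain
      a$x[sel] <- a$x[sel] + dirn[1]
      a$y[sel] <- a$y[sel] + dirn[2]
      a$z[sel] <- a$z[sel] + dirn[3]
      disp$chains$A[[i]]$atoms <- a
    }
    sc <- suppressWarnings(density_sum_score(disp, map, cfg)$total)
    if (native_score > sc) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})
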