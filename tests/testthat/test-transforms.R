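test_that("es = 1 and ds = 0 are exact identities; direct formulas hold", {
  tr <- small_bd_tree(seed = 8)
  y <- simulate_bm(tr, sigma2 = 2, root_value = 1, seed = 41)
  expect_identical(apply_trend(y, tr, 1), y)
  expect_identical(apply_drift(y, tr, 0), y)

  # hand-checked values: y = 3, t = 2, es = 2 -> 6; y = 1, t = 2, ds = 0.5 -> 2
  tr3 <- read_newick(nwk_cherry3)
  y3 <- c(A = 3, B = 1, C = -2)
  expect_equal(unname(apply_trend(y3, tr3, 2)["A"]), 3 * 2^2 / 2)
  expect_equal(unname(apply_drift(y3, tr3, 0.5)["B"]), 1 + 2 * 0.5)
})

test_that("trend transform inflates recent-tip variance when es > 1", {
  # full-size tree so the oldest third is genuinely ancient (mostly fossils)
  tr <- simulate_bd_tree(seed = 9)
  ages <- element_ages(tr)[seq_len(ape::Ntip(tr))]
  # age-order thirds (extant tips share the maximum age, so quantile bins
  # would degenerate); oldest vs most recent third by rank
  ord <- order(ages)
  k <- floor(length(ord) / 3)
  old_i <- ord[seq_len(k)]
  rec_i <- ord[(length(ord) - k + 1L):length(ord)]
  # marginal (across-replicate) tip variance is exactly t^(2 es - 1) sigma^2;
  # the Monte-Carlo ratio between recent and old thirds must match that
  # closed form
  Y2 <- sapply(1:200, function(i) apply_trend(simulate_bm(tr, sigma2 = 1,
                                                          seed = 4200 + i), tr, 1.8))
  v_tip <- apply(Y2, 1L, var)
  measured <- mean(v_tip[rec_i]) / mean(v_tip[old_i])
  theory <- mean(ages[rec_i]^(2 * 1.8 - 1)) / mean(ages[old_i]^(2 * 1.8 - 1))
  expect_gt(measured, 1)
  expect_lt(abs(measured / theory - 1), 0.3)
  # and per-replicate, the recent third spans a wider range than the old
  # third in the majority of draws (tips are phylogenetically correlated, so
  # this is noisier than the marginal-variance comparison above)
  hits <- apply(Y2, 2L, function(y2) diff(range(y2[rec_i])) > diff(range(y2[old_i])))
  expect_gt(mean(hits), 0.5)
})

test_that("clade transforms touch only the clade and follow their formulas", {
  tr <- small_bd_tree(seed = 10)
  n_tip <- ape::Ntip(tr)
  node <- n_tip + 3L
  cl <- clade_members(tr, node)
  y <- simulate_bm(tr, sigma2 = 1.5, root_value = -2, seed = 43)
  out <- !(names(y) %in% cl$tip_labels)

  y_tr <- apply_clade_trend(y, tr, cl, es_sig = 1.6)
  expect_identical(y_tr[out], y[out])
  ages <- element_ages(tr)[seq_len(n_tip)]
  sel <- names(y) %in% cl$tip_labels
  expect_equal(y_tr[sel], y[sel] * ages[sel]^3.2 / ages[sel], tolerance = 1e-12)

  y_dr <- apply_clade_drift(y, tr, cl, ds_sig = 0.25)
  expect_identical(y_dr[out], y[out])
  # algebraic inversion: mean clade displacement recovers 2 ds_sig H_ratio exactly
  disp <- mean((y_dr[sel] - y[sel]) / ages[sel])
  expect_equal(disp, 2 * 0.25 * cl$H_ratio, tolerance = 1e-9)
  # whole-tree clade degenerates to the global transforms
  root_cl <- clade_members(tr, n_tip + 1L)
  expect_equal(apply_clade_trend(y, tr, root_cl, 0.8), apply_trend(y, tr, 1.6))
  expect_equal(apply_clade_drift(y, tr, root_cl, 0.3),
               apply_drift(y, tr, 2 * 0.3 * root_cl$H_ratio))
})

test_that("dev is zero without drift, exactly odd in ds, and linear in ds", {
  tr <- small_bd_tree(seed = 12)
  y <- simulate_bm(tr, sigma2 = 3, root_value = 4, seed = 44)
  expect_identical(dev_metric(y, y, tr), 0)
  dp <- dev_metric(y, apply_drift(y, tr, 0.4), tr)
  dm <- dev_metric(y, apply_drift(y, tr, -0.4), tr)
  expect_equal(dp, -dm, tolerance = 1e-12)
  d2 <- dev_metric(y, apply_drift(y, tr, 0.8), tr)
  expect_equal(d2, 2 * dp, tolerance = 1e-12)
  # with known sigma, dev equals ds * mean(tip age) / height exactly
  ages <- element_ages(tr)[seq_len(ape::Ntip(tr))]
  d_known <- dev_metric(y, apply_drift(y, tr, 0.25 * 2), tr, sigma = 2)
  expect_equal(d_known, 0.25 * mean(ages) / tree_height(tr), tolerance = 1e-9)
})

test_that("dev grows with tree height before the per-time normalization", {
  # same topology, stretched branches: the accumulated displacement doubles
  tr <- read_newick(nwk_cherry3)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  y <- c(A = 0.3, B = -0.1, C = 0.2)
  d1 <- dev_metric(y, apply_drift(y, tr, 0.25), tr, sigma = 1) * tree_height(tr)
  d2 <- dev_metric(y, apply_drift(y, tr2, 0.25), tr2, sigma = 1) * tree_height(tr2)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("spread self-normalizes in the mean under BM and increases with es", {
  tr <- small_bd_tree(seed = 13, n_extant = 40, min_tips = 30)
  vals <- vapply(1:20, function(i) {
    sim <- simulate_bm(tr, sigma2 = 1, seed = 500 + i, internal = TRUE)
    spread_metric(sim, tr, attr(sim, "node_values"), n_bm_reference = 50,
                  seed = 600 + i)
  }, numeric(1))
  # per-replicate spread is noisy (it is a ratio of ranges), but the
  # BM-reference normalization centres it on 1
  expect_gt(mean(vals), 0.7)
  expect_lt(mean(vals), 1.3)

  # monotone in es (true node values transformed by their own ages)
  ages <- element_ages(tr)
  n_tip <- ape::Ntip(tr)
  sp_at <- function(es) {
    mean(vapply(1:10, function(i) {
      sim <- simulate_bm(tr, sigma2 = 1, seed = 700 + i, internal = TRUE)
      nv <- attr(sim, "node_values")
      t_node <- ages[n_tip + seq_len(tr$Nnode)]
      nv2 <- ifelse(t_node > 0, nv * t_node^es / t_node, nv)
      names(nv2) <- names(nv)
      spread_metric(apply_trend(sim, tr, es), tr, nv2,
                    n_bm_reference = 50, seed = 800 + i)
    }, numeric(1)))
  }
  sp <- c(sp_at(0.3), sp_at(1), sp_at(1.6))
  expect_lt(sp[1], 1)
  expect_gt(sp[3], 1)
  expect_true(all(diff(sp) > 0))
})
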