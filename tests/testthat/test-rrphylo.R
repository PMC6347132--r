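test_that("rootV is the documented weighted mean of the most ancient tips", {
  tr <- small_bd_tree(seed = 14)
  y <- simulate_bm(tr, sigma2 = 1, seed = 51)
  # constant selected values -> rootV equals that constant whatever the weights
  y_const <- y; y_const[] <- 2.25
  expect_equal(estimate_rootV(tr, y_const), 2.25)

  # independent arithmetic on a hand-built selection (30% of 10 tips = 3 tips)
  tr10 <- read_newick("(((A:1,B:2):1,(C:3,D:1):2):1,((E:2,F:3):2,(G:1,H:4):1):2);")
  y10 <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8), LETTERS[1:8])
  ages <- element_ages(tr10)[names(y10)]
  sel <- names(sort(ages))[1:max(1, round(0.3 * 8))]
  expect_equal(estimate_rootV(tr10, y10, fraction = 0.3),
               sum(y10[sel] / ages[sel]^2) / sum(1 / ages[sel]^2))
  expect_equal(estimate_rootV(tr10, y10, fraction = 0.3, weighting = "square_age"),
               sum(y10[sel] * ages[sel]^2) / sum(ages[sel]^2))
})

test_that("design matrix encodes root-path branch lengths", {
  pair <- read_newick(nwk_pair)
  L <- build_design_matrix(pair)
  expect_equal(unname(L[c("A", "B"), c("A", "B")]),
               matrix(c(1, 0, 0, 2), 2, byrow = TRUE))
  for (s in 1:10) {
    tr <- small_bd_tree(seed = 400 + s)
    L <- build_design_matrix(tr)
    expect_equal(rowSums(L), element_ages(tr), tolerance = 1e-12)
    # independent path enumeration for a handful of tips
    ctx_labels <- colnames(L)
    for (tip in c(1L, ape::Ntip(tr))) {
      cur <- tip
      expected <- setNames(numeric(ncol(L)), ctx_labels)
      while (cur != ape::Ntip(tr) + 1L) {
        row <- which(tr$edge[, 2L] == cur)
        lab <- c(tr$tip.label, tr$node.label)[cur]
        expected[lab] <- tr$edge.length[row]
        cur <- tr$edge[row, 1L]
      }
      expect_equal(L[tip, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("ridge solution matches the normal-equations oracle", {
  tr5 <- read_newick("(((A:1,B:1.5):0.5,C:2):1,(D:1,E:2.5):0.5);")
  set.seed(52)
  y <- setNames(rnorm(5), LETTERS[1:5])
  L <- build_design_matrix(tr5)[1:5, ]
  for (lam in c(0.01, 1, 50)) {
    fit <- fit_rates(tr5, y, lambda = lam)
    b_oracle <- solve(t(L) %*% L + lam * diag(ncol(L)),
                      t(L) %*% (y - fit$rootV))
    expect_equal(unname(fit$rates), as.vector(b_oracle), tolerance = 1e-8)
  }
})

test_that("degenerate and decoupled cases are exact", {
  # all tips at rootV: zero residual, zero rates, node estimates at rootV
  tr <- small_bd_tree(seed = 15)
  y0 <- setNames(rep(1.5, ape::Ntip(tr)), tr$tip.label)
  f0 <- fit_rates(tr, y0, lambda = 3)
  expect_equal(unname(f0$rates), rep(0, length(f0$rates)), tolerance = 1e-10)
  expect_equal(unname(f0$node_estimates), rep(1.5, tr$Nnode), tolerance = 1e-10)

  # 2-tip, lambda = 0, rootV fixed at 0: diagonal system solves exactly
  pair <- read_newick(nwk_pair)
  fp <- fit_rates(pair, c(A = 1, B = 4), lambda = 0, rootV = 0)
  expect_equal(unname(fp$rates[c("A", "B")]), c(1, 2), tolerance = 1e-10)
})

test_that("model identity: estimates are rootV plus path-summed rates", {
  tr <- small_bd_tree(seed = 16)
  y <- simulate_bm(tr, sigma2 = 2, root_value = -3, seed = 53)
  fit <- fit_rates(tr, y)
  L <- build_design_matrix(tr)
  n_tip <- ape::Ntip(tr)
  expect_equal(unname(fit$node_estimates),
               unname(fit$rootV + L[(n_tip + 1):nrow(L), ] %*% fit$rates)[, 1],
               tolerance = 1e-10)
  expect_equal(unname(fit$fitted),
               unname(fit$rootV + L[1:n_tip, ] %*% fit$rates)[, 1],
               tolerance = 1e-10)
  ph <- predict_phenotype_vector(fit)
  expect_equal(nrow(ph), n_tip + tr$Nnode)
  expect_equal(ph$value[ph$element == tr$node.label[1L]], fit$rootV)
})

test_that("penalty increases shrink the rate vector norm", {
  tr <- small_bd_tree(seed = 17)
  y <- simulate_bm(tr, sigma2 = 1, seed = 54)
  lams <- c(0.001, 0.1, 10, 1000)
  norms <- vapply(lams, function(l) sqrt(sum(fit_rates(tr, y, lambda = l)$rates^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("auto penalty fits BM tips closely and rates grow with age under BM", {
  cors <- sp <- numeric(12)
  for (s in 1:12) {
    tr <- small_bd_tree(seed = 420 + s, n_extant = 40, min_tips = 30)
    y <- simulate_bm(tr, sigma2 = 1, seed = 55 + s)
    fit <- fit_rates(tr, y)
    cors[s] <- cor(fit$fitted, y)
    ages <- element_ages(tr)
    branch_ages <- ages[names(fit$rates)]
    sp[s] <- cor(abs(fit$rates), branch_ages, method = "spearman")
  }
  expect_gte(mean(cors > 0.95), 0.9)
  # rate magnitude increases towards the present in the clear majority of trees
  expect_gt(mean(sp > 0), 0.75)
})

test_that("ancestral estimates degrade from tips towards the root", {
  agree <- vapply(1:10, function(s) {
    tr <- simulate_bd_tree(birth = 0.5, death = 0, min_tips = 25, seed = 440 + s,
                           n_extant = 30)
    sim <- simulate_bm(tr, sigma2 = 1, seed = 56 + s, internal = TRUE)
    fit <- fit_rates(tr, sim)
    err <- abs(fit$node_estimates - attr(sim, "node_values")[names(fit$node_estimates)])
    depth_from_tips <- tree_height(tr) - element_ages(tr)[names(err)]
    cor(err, depth_from_tips, method = "spearman")
  }, numeric(1))
  expect_gt(mean(agree > 0), 0.7)
})
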