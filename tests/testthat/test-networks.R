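toy_eigengene <- function(values, kind, name = colnames(values)) {
  structure(list(values = values,
                 variance_explained = stats::setNames(rep(1, ncol(values)),
                                                      colnames(values)),
                 module_sizes = stats::setNames(rep(2L, ncol(values)),
                                                colnames(values)),
                 kind = kind),
            class = "eigengene_matrix")
}

test_that("module eigengenes solve the analytic two-feature cases", {
  n <- 30
  pat <- sin(seq_len(n))
  samples <- sprintf("s%02d", seq_len(n))
  # rank-1 module: two identical features
  X <- cbind(a = pat, b = pat, c = -pat, d = pat + 0 * pat)
  rownames(X) <- samples
  x <- omics_matrix(X, "immune")
  eg <- module_eigengene(x, c(a = "blue", b = "blue", c = "brown", d = "brown"))
  zpat <- as.numeric(scale(pat))
  expect_equal(abs(cor(eg$values[, "blue"], pat)), 1, tolerance = 1e-9)
  expect_gt(cor(eg$values[, "blue"], pat), 0)        # sign convention
  expect_equal(unname(eg$variance_explained["blue"]), 1, tolerance = 1e-9)
  expect_equal(sd(eg$values[, "blue"]), 1, tolerance = 1e-9)
  # antipodal module: eigengene correlates +1 / -1 with its members
  expect_equal(unname(eg$variance_explained["brown"]), 1, tolerance = 1e-9)
  expect_equal(abs(cor(eg$values[, "brown"], X[, "c"])), 1, tolerance = 1e-9)
  expect_equal(abs(cor(eg$values[, "brown"], X[, "d"])), 1, tolerance = 1e-9)
})

test_that("an isotropic two-feature module explains about half the variance", {
  ve <- symptomics:::with_seed(51, {
    replicate(5, {
      X <- matrix(rnorm(1000), 500, 2,
                  dimnames = list(sprintf("s%03d", 1:500), c("u", "v")))
      eg <- module_eigengene(omics_matrix(X, "blood"), c(u = "m", v = "m"))
      eg$variance_explained[["m"]]
    })
  })
  expect_lt(abs(mean(ve) - 0.5), 0.1)
})

test_that("eigengenes are invariant to member order and handle singletons", {
  set.seed(52)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(sprintf("s%02d", 1:40), letters[1:4]))
  X[, 2] <- X[, 1] + rnorm(40, 0, 0.3)
  x <- omics_matrix(X, "immune")
  asg <- c(a = "m1", b = "m1", c = "m1", d = "solo")
  e1 <- module_eigengene(x, asg)
  xp <- omics_matrix(X[, c(3, 1, 4, 2)], "immune")
  e2 <- module_eigengene(xp, asg)
  expect_equal(abs(cor(e1$values[, "m1"], e2$values[, "m1"])), 1,
               tolerance = 1e-9)
  # singleton passes through standardized
  expect_equal(unname(e1$values[, "solo"]),
               as.numeric(scale(X[, "d"])) / sd(scale(X[, "d"])),
               tolerance = 1e-9)
  expect_equal(unname(e1$variance_explained["solo"]), 1)
  expect_error(module_eigengene(x, c(a = "m1")), "missing")
})

test_that("edges obey the inclusive |rho| >= 0.3 rule", {
  n <- 40
  base <- seq_len(n)
  # perturb a copy of `base` by seeded swaps until Spearman rho crosses the
  # target band; deterministic given the seed
  craft <- function(lo, hi, seed) {
    symptomics:::with_seed(seed, {
      y <- base
      repeat {
        r <- cor(base, y, method = "spearman")
        if (r >= lo && r < hi) return(y)
        if (r < lo) y <- base  # overshot; restart
        i <- sample(n, 2)
        y[i] <- y[rev(i)]
      }
    })
  }
  y_in <- craft(0.30, 0.32, 3)   # just above threshold
  y_out <- craft(0.28, 0.295, 4) # just below
  samples <- sprintf("s%02d", seq_len(n))
  E1 <- toy_eigengene(matrix(base, dimnames = list(samples, "hub")), "immune")
  E2 <- toy_eigengene(cbind(yin = y_in, yout = y_out, same = base) * 1.0,
                      "metabolome")
  rownames(E2$values) <- samples
  net <- correlation_network(list(E1, E2), threshold = 0.3)
  key <- function(a, b) any(net$edges$node1 == a & net$edges$node2 == b |
                              net$edges$node1 == b & net$edges$node2 == a)
  expect_true(key("immune.hub", "metabolome.yin"))
  expect_false(key("immune.hub", "metabolome.yout"))
  # identical values across kinds: rho = 1 edge
  expect_true(key("immune.hub", "metabolome.same"))
  expect_equal(net$edges$rho[net$edges$node2 == "metabolome.same" |
                               net$edges$node1 == "metabolome.same"][1], 1)
  # stored edges never violate the threshold; p-values are Holm-adjusted
  expect_true(all(abs(net$edges$rho) >= 0.3))
  expect_true(all(net$edges$p_adj >= net$edges$p - 1e-15))
  expect_error(correlation_network(list(
    toy_eigengene(matrix(1:2, dimnames = list(c("a", "b"), "m")), "immune")),
    threshold = 0.3), "3 shared")
})

test_that("a planted star network puts maximal betweenness on its hub", {
  leaves <- symptomics:::with_seed(53, {
    q <- qr.Q(qr(matrix(rnorm(200 * 4), 200, 4)))
    dimnames(q) <- list(sprintf("s%03d", 1:200), paste0("leaf", 1:4))
    q
  })
  hub <- rowSums(leaves)
  E1 <- toy_eigengene(matrix(hub, dimnames = list(rownames(leaves), "hub")),
                      "immune")
  E2 <- toy_eigengene(leaves, "metabolome")
  net <- correlation_network(list(E1, E2), threshold = 0.3)
  expect_equal(nrow(net$edges), 4)  # hub-leaf edges only
  bt <- stats::setNames(net$nodes$betweenness, net$nodes$node)
  expect_equal(unname(bt["immune.hub"]), choose(4, 2))  # exact star value
  expect_true(all(bt[names(bt) != "immune.hub"] == 0))
  dg <- stats::setNames(net$nodes$degree, net$nodes$node)
  expect_equal(unname(dg["immune.hub"]), 4)
})

test_that("differential networks difference pre-threshold correlations", {
  mk_net <- function(r12, r13) {
    rho <- diag(3)
    dimnames(rho) <- list(c("a", "b", "c"), c("a", "b", "c"))
    rho["a", "b"] <- rho["b", "a"] <- r12
    rho["a", "c"] <- rho["c", "a"] <- r13
    structure(list(nodes = data.frame(node = c("a", "b", "c")),
                   edges = data.frame(), rho_full = rho, threshold = 0.3),
              class = "correlation_network")
  }
  net_s <- mk_net(0.6, 0.4)
  net_r <- mk_net(0.1, -0.4)
  d <- differential_network(net_s, net_r, delta = 0.3)
  ab <- d[d$node1 == "a" & d$node2 == "b", ]
  expect_equal(ab$delta_rho, 0.5)            # 0.6 - 0.1, below-threshold ref
  expect_identical(ab$direction, "increased")
  ac <- d[d$node1 == "a" & d$node2 == "c", ]
  expect_equal(ac$delta_rho, 0.8)
  expect_identical(ac$direction, "reversed") # sign flip -0.4 -> 0.4
  # self-comparison is empty for any positive delta
  expect_equal(nrow(differential_network(net_s, net_s, delta = 0.05)), 0)
  net_bad <- mk_net(0, 0)
  rownames(net_bad$rho_full) <- colnames(net_bad$rho_full) <- c("a", "b", "z")
  expect_error(differential_network(net_s, net_bad), "z")
})

test_that("spearman edges are invariant to monotone transforms", {
  set.seed(54)
  u <- rnorm(50); v <- 0.8 * u + rnorm(50, 0, 0.5)
  samples <- sprintf("s%02d", 1:50)
  mk <- function(vals, kind, nm) {
    m <- matrix(vals, dimnames = list(samples, nm))
    toy_eigengene(m, kind)
  }
  n1 <- correlation_network(list(mk(u, "immune", "m"),
                                 mk(v, "metabolome", "w")))
  n2 <- correlation_network(list(mk(exp(u), "immune", "m"),
                                 mk(v^3, "metabolome", "w")))
  expect_equal(n1$rho_full["immune.m", "metabolome.w"],
               n2$rho_full["immune.m", "metabolome.w"], tolerance = 1e-12)
})
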