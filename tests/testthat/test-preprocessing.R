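# Expected values for probe aggregation frozen from the order-statistic
# convention (linear interpolation, type 7): for {1, 2, 10} at p = 0.9 the
# index is 1 + 0.9 * 2 = 2.8, i.e. 2 + 0.8 * (10 - 2) = 8.4.
test_that("probe aggregation takes the 90th percentile of unique probes", {
  pm <- matrix(c(1, 2, 10, 5, 6, 7), nrow = 3,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- data.frame(probe_id = c("p1", "p2", "p3"), gene_id = "G1")
  out <- aggregate_probes(pm, map)
  expect_equal(out["G1", ], c(s1 = 8.4, s2 = 6.8))

  single <- aggregate_probes(pm, data.frame(probe_id = "p2", gene_id = "G1"))
  expect_equal(single["G1", ], pm["p2", ])
})

test_that("multi-gene probes are discarded unless they are a gene's only probes", {
  pm <- matrix(c(1, 2, 3, 9), nrow = 4,
               dimnames = list(paste0("p", 1:4), "s1"))
  map <- data.frame(
    probe_id = c("p1", "p2", "p2", "p3", "p4"),
    gene_id  = c("G1", "G1", "G2", "G2", "G3")
  )
  out <- aggregate_probes(pm, map)
  # p2 maps to G1 and G2: dropped for G1 (has p1) and for G2 (has p3)
  expect_equal(out["G1", "s1"], 1)
  expect_equal(out["G2", "s1"], 3)
  expect_equal(out["G3", "s1"], 9)

  # gene whose only coverage is multi-gene probes: median of those probes
  map2 <- data.frame(probe_id = c("p1", "p2", "p1", "p2", "p3"),
                     gene_id = c("G1", "G1", "G2", "G2", "G1"))
  out2 <- aggregate_probes(pm, map2)
  expect_equal(out2["G2", "s1"], stats::median(c(1, 2)))

  expect_error(aggregate_probes(pm, data.frame(probe_id = "px", gene_id = "G9")),
               class = "empty_mapping_error")
})

test_that("quantile normalization replaces columns by rank-wise means", {
  # columns [1,2,3] and [4,5,6] on the post-log scale: both become [2.5,3.5,4.5]
  m <- cbind(s1 = expm1(c(1, 2, 3)), s2 = expm1(c(4, 5, 6)))
  rownames(m) <- paste0("g", 1:3)
  out <- log_truncate_quantile_normalize(m, q_low = 0, q_high = 1)
  expect_equal(unname(out[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "s2"]), c(2.5, 3.5, 4.5))
})

test_that("quantile normalization agrees with the limma reference implementation", {
  set.seed(11)
  m <- matrix(rlnorm(400, meanlog = 2), nrow = 80,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:5)))
  got <- log_truncate_quantile_normalize(m, q_low = 0, q_high = 1)
  ref <- limma::normalizeQuantiles(log1p(m), ties = TRUE)
  expect_equal(unname(got), unname(as.matrix(ref)), tolerance = 1e-12)
})

test_that("quantile normalization makes column order statistics identical", {
  set.seed(12)
  m <- matrix(rlnorm(600), nrow = 100)
  dimnames(m) <- list(paste0("g", 1:100), paste0("s", 1:6))
  # no truncation: clamping introduces ties, whose rank-averaged values are
  # the one documented departure from identical order statistics
  out <- log_truncate_quantile_normalize(m, q_low = 0, q_high = 1)
  sorted <- apply(out, 2, sort)
  for (j in 2:ncol(sorted)) {
    expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  }
})

test_that("truncation clamps exactly at the global quantile bounds", {
  set.seed(13)
  m <- matrix(rlnorm(500), nrow = 100, dimnames = list(paste0("g", 1:100), NULL))
  colnames(m) <- paste0("s", 1:5)
  l <- log1p(m)
  bounds <- quantile(l, c(0.01, 0.99), type = 7, names = FALSE)
  model <- fit_normalization(m, rescale = "none")
  expect_equal(model$trunc_bounds, bounds)
  # a value far above the 0.99 quantile lands exactly on the bound pre-QN
  m2 <- m
  m2[1, 1] <- max(m) * 100
  clamped <- pmin(pmax(log1p(m2), bounds[1]), bounds[2])
  expect_equal(clamped[1, 1], bounds[2])
})

test_that("an all-constant matrix passes through with a warning", {
  m <- matrix(0, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_warning(out <- log_truncate_quantile_normalize(m),
                 class = "degenerate_matrix_warning")
  expect_true(all(out == 0))
})

test_that("unit-interval rescaling maps min to 0 and max to 1", {
  m <- matrix(c(0, 5, 10, 2, 3, 6), nrow = 3)
  expect_equal(rescale_unit_interval(matrix(c(0, 5, 10), 3, 1))[, 1],
               c(0, 0.5, 1))
  expect_equal(rescale_unit_interval(matrix(c(2, 3, 6), 3, 1))[2, 1], 0.25)
  expect_warning(out <- rescale_unit_interval(matrix(7, 2, 2)),
                 class = "degenerate_matrix_warning")
  expect_true(all(out == 0.5))
})

test_that("rescaling is idempotent in scale", {
  set.seed(14)
  m <- matrix(runif(60, 0, 50), nrow = 10)
  once <- rescale_unit_interval(m)
  expect_equal(rescale_unit_interval(once), once, tolerance = 1e-15)
})

test_that("the full chain is column-permutation equivariant and lands in [0,1]", {
  set.seed(15)
  m <- matrix(rlnorm(480, meanlog = 2), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  out <- normalize_expression(m)$values
  expect_true(all(out >= 0 & out <= 1))
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  out_perm <- normalize_expression(m[, perm])$values
  expect_equal(out_perm, out[, perm], tolerance = 1e-12)
})

test_that("a frozen normalization model reproduces the reference transform", {
  set.seed(16)
  m <- matrix(rlnorm(300, meanlog = 2), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  norm <- normalize_expression(m)
  expect_equal(apply_normalization(norm$model, m), norm$values)
})

test_that("node values aggregate member genes and default missing nodes", {
  g <- pathway_graph("P",
    nodes = data.frame(node_id = c("A", "B", "C"), label = c("A", "B", "C"),
                       genes = I(list("g1", c("g2", "g3"), "g9"))),
    edges = edge_df(c("A", "B"), c("B", "C"))
  )
  m <- matrix(c(0.3, 0.2, 0.8, 0.7, 0.4, 0.6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  nv <- compute_node_values(m, g, aggregator = "mean")
  expect_equal(nv["A", ], m["g1", ])                      # single gene: passthrough
  expect_equal(unname(nv["B", ]), c((0.8 + 0.4) / 2, (0.7 + 0.6) / 2))
  expect_equal(unname(nv["C", ]), c(0.5, 0.5))            # unmeasured: default
  expect_equal(attr(nv, "defaulted_nodes"), "C")

  nv90 <- compute_node_values(m, g)  # default: 90th percentile
  expect_equal(unname(nv90["B", "s1"]),
               quantile(c(0.8, 0.4), 0.9, type = 7, names = FALSE))

  expect_error(compute_node_values(m * 10, g), class = "domain_error")
})
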