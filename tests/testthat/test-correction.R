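edge_row <- function(x, y, r, syx, sxy) {
  data.frame(node_x = x, node_y = y, r = r, p = 1e-6,
             slope_y_on_x = syx, slope_x_on_y = sxy,
             beta = atan(syx), stringsAsFactors = FALSE)
}

# a fully connected admissible chain over all 24 nodes with unit slopes,
# overridden by the supplied edges (placed first, highest |r|)
chain_edges <- function(...) {
  nodes <- likertcirc:::node_names()
  chain <- do.call(rbind, lapply(seq_len(23), function(i) {
    edge_row(nodes[i], nodes[i + 1], 0.8 - i * 1e-3, 1, 1)
  }))
  over <- list(...)
  if (length(over) > 0) rbind(do.call(rbind, over), chain) else chain
}

test_that("propagation multiplies directional slopes along the spanning tree", {
  # single edge, paper-style: slope(pleasant.A on pleasant.D) = -0.74
  e <- chain_edges(edge_row("pleasant.D", "pleasant.A", -0.9, -0.74, -0.74))
  p <- propagate_values(e)
  expect_equal(unname(p$values["pleasant.D"]), -1)
  expect_equal(unname(p$values["pleasant.A"]), 0.74)

  # chain: anchor -1 -> (slope 1.33) -> node2 -> (slope 0.5) -> node3
  e <- chain_edges(
    edge_row("pleasant.D", "annoying.A", -0.99, 1.33, 0.6),
    edge_row("annoying.A", "calm.D", -0.95, 0.5, 1.2))
  p <- propagate_values(e)
  expect_equal(unname(p$values["annoying.A"]), -1.33)
  expect_equal(unname(p$values["calm.D"]), -0.665)
})

test_that("propagation reports unreachable neutrals and fails on missing poles", {
  nodes <- likertcirc:::node_names()
  poles <- nodes[!grepl("\\.N$", nodes)]
  e <- do.call(rbind, lapply(seq_len(15), function(i) {
    edge_row(poles[i], poles[i + 1], 0.9 - i * 1e-3, 1, 1)
  }))
  p <- propagate_values(e)
  expect_setequal(p$unreachable, nodes[grepl("\\.N$", nodes)])
  expect_true(all(!is.na(p$values[poles])))

  # dropping the pole chain disconnects pole nodes -> hard error
  expect_error(propagate_values(e[1:10, ]), class = "lc_error_disconnected")
  expect_error(propagate_values(e[0, ]), class = "lc_error_disconnected")
})

test_that("propagation is invariant to edge input order", {
  set.seed(7)
  e <- chain_edges(edge_row("pleasant.D", "monotonous.A", -0.85, 0.7, 0.9))
  p0 <- propagate_values(e)
  for (i in 1:5) {
    ps <- propagate_values(e[sample(nrow(e)), ])
    expect_identical(ps$values, p0$values)
    expect_identical(ps$spanning_edges, p0$spanning_edges)
  }
})

test_that("angle mode applies the arctangent dilation factor", {
  e <- chain_edges(edge_row("pleasant.D", "pleasant.A", -0.9, -0.74, -0.74))
  p <- propagate_values(e, mode = "angle")
  expect_equal(unname(p$values["pleasant.A"]), atan(0.74) / (pi / 4))
})

test_that("neutral sign follows the N-vs-A / N-vs-D correlation comparison", {
  t <- seq(-1, 1, length.out = 9)
  gp <- make_gp(list(pleasant.N = 50 + 10 * t, pleasant.A = 30 + 20 * t,
                     pleasant.D = 40 - 15 * t), 9)
  expect_equal(neutral_sign(gp, "pleasant"), 1)   # N rises exactly with A
  gp2 <- make_gp(list(pleasant.N = 50 + 10 * t, pleasant.A = 30 - 20 * t,
                      pleasant.D = 40 + 15 * t), 9)
  expect_equal(neutral_sign(gp2, "pleasant"), -1)
  # exact tie -> +1
  gp3 <- make_gp(list(pleasant.N = 50 + 10 * t, pleasant.A = 30 + 20 * t,
                      pleasant.D = 40 + 15 * t), 9)
  expect_equal(neutral_sign(gp3, "pleasant"), 1)
  gp4 <- make_gp(list(pleasant.N = rep(50, 9)), 9)
  expect_warning(z <- neutral_sign(gp4, "pleasant"), class = "lc_warning_neutral_sign")
  expect_equal(z, 1)
})

test_that("build_correction evaluates the metric formulas", {
  # symmetric case reduces to the equidistant metric
  row <- build_correction(a0 = 1, d0 = -1, n0 = 1, z = 1)
  expect_equal(unlist(row[c("dd", "d", "n", "a", "aa")], use.names = FALSE),
               c(-1, -0.5, 0, 0.5, 1))
  # asymmetric case, direct evaluation
  row <- build_correction(a0 = 0.8, d0 = -1, n0 = 0.3, z = -1)
  expect_equal(unlist(row[c("b", "aa", "dd", "n", "d", "a")], use.names = FALSE),
               c(-0.1, 0.9, -0.9, -0.1, -0.25, 0.05))
  expect_false(row$n0_fallback_used)
  # fallback midpoints
  row <- build_correction(a0 = 1, d0 = -1, n0 = NA, z = 1)
  expect_equal(unlist(row[c("b", "n", "d", "a")], use.names = FALSE),
               c(0, 0, -0.5, 0.5))
  expect_true(row$n0_fallback_used)
  # inverted scale keeps categories monotone and n0 width
  row <- build_correction(a0 = -0.8, d0 = 1, n0 = 0.3, z = 1)
  vals <- unlist(row[c("dd", "d", "n", "a", "aa")], use.names = FALSE)
  expect_true(all(diff(vals) < 0))
  expect_equal(abs(row$a - row$d), 0.3)

  expect_error(build_correction(0.5, 0.5), class = "lc_error_degenerate_scale")
})

test_that("derived corrections are centred (aa = -dd) and carry provenance", {
  truth <- synthetic_truth(n_sites = 20, seed = 5)
  tab <- generate_survey(truth, 60)
  ct <- suppressWarnings(suppressMessages(derive_correction(tab)))
  expect_equal(ct$aa, -ct$dd, tolerance = 1e-12)
  prov <- attr(ct, "provenance")
  expect_equal(prov$anchor_node, "pleasant.D")
  expect_equal(unname(ct["pleasant", "d0"]), -1)
  expect_true(nrow(prov$spanning_edges) >= 15)
  # n0 identity: when present, |a - d| = n0
  has <- !is.na(ct$n0)
  expect_equal(abs(ct$a[has] - ct$d[has]), ct$n0[has], tolerance = 1e-12)

  expect_error(derive_correction(make_record()), class = "lc_error_min_sites")
})

test_that("anchor scaling propagates through values but not coordinates", {
  truth <- synthetic_truth(n_sites = 20, seed = 6)
  tab <- generate_survey(truth, 60)
  ct1 <- suppressWarnings(suppressMessages(derive_correction(tab)))
  ct2 <- suppressWarnings(suppressMessages(
    derive_correction(tab, anchor_value = -2.5)))
  expect_equal(ct2$aa, 2.5 * ct1$aa, tolerance = 1e-9)
  expect_equal(ct2$n, 2.5 * ct1$n, tolerance = 1e-9)
  c1 <- apply_correction(tab[1:50, ], ct1)
  c2 <- apply_correction(tab[1:50, ], ct2)
  expect_equal(c1$pleasantness, c2$pleasantness, tolerance = 1e-9)
  expect_equal(c1$eventfulness, c2$eventfulness, tolerance = 1e-9)
})

test_that("apply_correction reproduces hand-computed coordinates", {
  ct <- identity_correction()
  rec <- make_record(pleasant = 5, annoying = 1, vibrant = 5, monotonous = 1,
                     calm = 5, chaotic = 1)
  cc <- apply_correction(rec, ct)
  expect_equal(cc$pleasantness, 1)
  expect_equal(cc$space, "corrected")
  # all-neutral record sits at the origin
  cc0 <- apply_correction(make_record(), ct)
  expect_equal(unlist(cc0[, c("pleasantness", "eventfulness")], use.names = FALSE),
               c(0, 0))

  # asymmetric single-attribute check against a spreadsheet-style sum
  ct_m <- as.data.frame(ct)
  ct_m[ct_m$attribute == "pleasant", c("dd", "d", "n", "a", "aa")] <-
    c(-0.9, -0.25, -0.1, 0.05, 0.9)
  ct_m <- correction_table(ct_m)
  rec2 <- make_record(pleasant = 2, annoying = 4, eventful = 5)
  cc2 <- apply_correction(rec2, ct_m)
  # valence: pleasant d (-0.25) + annoying a (-0.5) + four neutrals (0)
  # normaliser: 0.9 + 1 * 5
  expect_equal(cc2$pleasantness, (-0.25 - 0.5) / 5.9)
  expect_equal(cc2$eventfulness, 1 / 6)

  # degenerate: all-zero pleasant metric shrinks the normaliser but a
  # non-positive normaliser must error
  ct_bad <- as.data.frame(identity_correction())
  ct_bad[, c("dd", "d", "n", "a", "aa")] <-
    -abs(ct_bad[, c("dd", "d", "n", "a", "aa")])
  expect_error(apply_correction(rec, suppressWarnings(correction_table(ct_bad))),
               class = "lc_error_degenerate_correction")
})
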