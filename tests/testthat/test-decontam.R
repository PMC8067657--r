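rel_plate_2x2 <- function(vals, wells = c("A1", "A2")) {
  # two adjacent wells, arbitrary feature columns
  rel <- do.call(rbind, vals)
  rownames(rel) <- paste0("s", seq_along(vals))
  list(rel = rel, layout = plate_layout(rownames(rel), wells))
}

test_that("relative abundance normalizes rows and preserves all-zero samples", {
  m <- matrix(c(5L, 5L, 0L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  rel <- to_relative_abundance(m)
  expect_equal(rel["s1", ], c(f1 = 0.5, f2 = 0.5))
  expect_equal(rel["s2", ], c(f1 = 0, f2 = 0))
  set.seed(1)
  r <- matrix(rpois(200, 5) + 1L, 10, 20,
              dimnames = list(sprintf("s%d", 1:10), sprintf("f%d", 1:20)))
  expect_equal(unname(rowSums(to_relative_abundance(r))), rep(1, 10))
})

test_that("adjacency rule zeroes strictly-below-ratio entries and keeps the boundary", {
  p <- rel_plate_2x2(list(c(f = 0.005, g = 0.995), c(f = 0.06, g = 0.94)))
  out <- apply_adjacency_filter(p$rel, p$layout, adjacency_ratio = 0.1)
  expect_equal(out$rel["s1", "f"], 0)          # 0.005 < 0.1 * 0.06
  expect_equal(out$report$rule, "adjacency")
  expect_equal(out$report$adjacent_sample, "s2")
  p2 <- rel_plate_2x2(list(c(f = 0.006, g = 0.994), c(f = 0.06, g = 0.94)))
  out2 <- apply_adjacency_filter(p2$rel, p2$layout, adjacency_ratio = 0.1)
  expect_equal(out2$rel["s1", "f"], 0.006)     # not strictly less: retained
  # entries with no occupied adjacent well are retained
  p3 <- rel_plate_2x2(list(c(f = 1e-5, g = 1 - 1e-5), c(f = 0.9, g = 0.1)),
                      wells = c("A1", "H12"))
  expect_equal(apply_adjacency_filter(p3$rel, p3$layout)$rel, p3$rel)
})

test_that("samples missing from the layout pass through with a warning, or error in strict mode", {
  p <- rel_plate_2x2(list(c(f = 0.001, g = 0.999), c(f = 0.06, g = 0.94)))
  rel <- rbind(p$rel, s3 = c(f = 1e-6, g = 1 - 1e-6))
  expect_warning(out <- apply_adjacency_filter(rel, p$layout), "s3")
  expect_equal(out$rel["s3", ], rel["s3", ])
  expect_error(apply_adjacency_filter(rel, p$layout, strict = TRUE), "s3")
})

test_that("adjacency filter matches the brute-force reference on random plates", {
  set.seed(42)
  for (trial in 1:25) {
    inst <- random_rel_plate(96, 50)
    mine <- apply_adjacency_filter(inst$rel, inst$layout, 0.1, "edge8")$rel
    expect_identical(mine, bf_adjacency_filter(inst$rel, inst$layout, 0.1, "edge8"))
    mine4 <- apply_adjacency_filter(inst$rel, inst$layout, 0.1, "edge4")$rel
    expect_identical(mine4, bf_adjacency_filter(inst$rel, inst$layout, 0.1, "edge4"))
  }
})

test_that("neighbour counts over the whole plate follow the grid geometry", {
  # 8 x 12 grid: 4 corners, 2*(8-2) + 2*(12-2) = 32 non-corner edge wells,
  # (8-2)*(12-2) = 60 interior wells
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  counts8 <- table(vapply(wells, function(w) length(adjacent_wells(w, "edge8")), 0L))
  expect_equal(as.integer(counts8[c("3", "5", "8")]), c(4L, 32L, 60L))
  counts4 <- table(vapply(wells, function(w) length(adjacent_wells(w, "edge4")), 0L))
  expect_equal(as.integer(counts4[c("2", "3", "4")]), c(4L, 32L, 60L))
})

test_that("abundance floor zeroes sub-floor entries, retains the boundary, and reports", {
  rel <- matrix(c(0.0019, 0.002, 0.9981, 0.998), 2, 2,
                dimnames = list(c("s1", "s2"), c("f1", "f2")))
  rel <- rbind(rel["s1", , drop = FALSE], rel["s2", , drop = FALSE])
  out <- apply_abundance_floor(rel, 0.002)
  expect_equal(out$rel["s1", "f1"], 0)
  expect_equal(out$rel["s2", "f1"], 0.002)
  expect_equal(out$report$rule, "floor")
  big <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("s1", c("f1", "f2")))
  expect_equal(apply_abundance_floor(big, 0.002)$rel, big)
})

test_that("both filters are idempotent and monotone in their thresholds", {
  set.seed(7)
  inst <- random_rel_plate(24, 30)
  a1 <- apply_adjacency_filter(inst$rel, inst$layout)$rel
  expect_identical(apply_adjacency_filter(a1, inst$layout)$rel, a1)
  f1 <- apply_abundance_floor(inst$rel)$rel
  expect_identical(apply_abundance_floor(f1)$rel, f1)
  # raising a threshold never restores a zeroed entry
  loose <- apply_adjacency_filter(inst$rel, inst$layout, 0.05)$rel
  tight <- apply_adjacency_filter(inst$rel, inst$layout, 0.2)$rel
  expect_true(all(tight[loose == 0] == 0))
  expect_true(all(apply_abundance_floor(inst$rel, 0.005)$rel[f1 == 0] == 0))
})

test_that("filter order does not change the final table, only the report attribution", {
  # with ratio < 1 an adjacency trigger large enough to zero an above-floor
  # entry survives the floor itself, so both orders agree on the output
  set.seed(8)
  for (trial in 1:20) {
    inst <- random_rel_plate(48, 30)
    af <- apply_abundance_floor(apply_adjacency_filter(inst$rel, inst$layout)$rel)$rel
    fa <- apply_adjacency_filter(apply_abundance_floor(inst$rel)$rel, inst$layout)$rel
    expect_identical(af, fa)
  }
  # attribution of an entry below both thresholds depends on the order
  p <- rel_plate_2x2(list(c(f = 0.0010, g = 0.9990), c(f = 0.06, g = 0.94)))
  adj_first <- apply_adjacency_filter(p$rel, p$layout)
  expect_equal(adj_first$report$rule, "adjacency")
  flo_first <- apply_abundance_floor(p$rel)
  expect_true("floor" %in% flo_first$report$rule &&
                "f" %in% flo_first$report$feature_id)
})

test_that("contaminants planted by the plate simulator are removed and true members kept", {
  sim <- simulate_plate(plate_sim_params(n_wells = 48, pool_size = 300, seed = 21))
  rel <- to_relative_abundance(sim$counts)
  out <- apply_adjacency_filter(rel, sim$layout, 0.1, "edge8")$rel
  contam <- sim$truth$contaminants
  removed_ok <- kept_bad <- 0L
  well_of <- setNames(sim$layout$well, sim$layout$sample_id)
  max_adj <- function(s, f) {
    nb <- sim$layout$sample_id[sim$layout$well %in% adjacent_wells(well_of[[s]])]
    max(rel[nb, f])
  }
  for (k in seq_len(nrow(contam))) {
    s <- contam$receiver[k]; f <- contam$feature_id[k]
    if (rel[s, f] > 0 && rel[s, f] < 0.1 * max_adj(s, f)) {
      removed_ok <- removed_ok + (out[s, f] == 0)
    }
  }
  # every contaminant entry meeting the strict-inequality condition is zeroed
  cond <- vapply(seq_len(nrow(contam)), function(k) {
    s <- contam$receiver[k]; f <- contam$feature_id[k]
    rel[s, f] > 0 && rel[s, f] < 0.1 * max_adj(s, f)
  }, TRUE)
  expect_equal(removed_ok, sum(cond))
  # no true-member entry at or above its retention condition is zeroed
  for (s in rownames(rel)) {
    for (f in names(sim$truth$members[[s]])) {
      if (rel[s, f] >= 0.002 && rel[s, f] >= 0.1 * max_adj(s, f))
        kept_bad <- kept_bad + (out[s, f] == 0)
    }
  }
  expect_equal(kept_bad, 0L)
})

test_that("host and organelle features are excluded with per-sample totals", {
  counts <- matrix(c(900L, 50L, 50L, 800L, 100L, 100L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("host", "het1", "het2")))
  tax <- taxonomy_table(c("host", "het1", "het2"),
                        genus = c("Prochlorococcus", "SAR11", "Alteromonas"))
  ex <- exclude_features(counts, tax, "host")
  expect_equal(colnames(ex$counts), c("het1", "het2"))
  expect_equal(ex$excluded$host_reads, c(900, 800))
  # no flagged features: identity
  tax2 <- taxonomy_table(c("host", "het1", "het2"), genus = "X")
  expect_identical(exclude_features(counts, tax2, "both")$counts, counts)
  # mixed host + organelle
  counts5 <- cbind(counts, chl = c(10L, 20L), host2 = c(5L, 5L))
  tax5 <- taxonomy_table(colnames(counts5),
                         genus = c("Prochlorococcus", "", "", "", "Synechococcus"),
                         family = c("", "", "", "Chloroplast", ""))
  expect_equal(ncol(exclude_features(counts5, tax5, "both")$counts), 2L)
  expect_error(exclude_features(counts, tax[1:2, ], "host"), "het2")
})

test_that("host normalization divides by host totals and flags zero-host samples", {
  het <- matrix(c(50L, 10L), 2, 1, dimnames = list(c("s1", "s2"), "f1"))
  hn <- host_normalize(het, c(s1 = 1000, s2 = 0))
  expect_equal(hn$ratios["s1", "f1"], 0.05)
  expect_true(is.na(hn$ratios["s2", "f1"]))
  expect_equal(hn$flagged, "s2")
  hn10 <- host_normalize(het * 10L, c(s1 = 10000, s2 = 0))
  expect_equal(hn10$ratios["s1", ], hn$ratios["s1", ])
})

test_that("mock calibration recommends the smallest floor that removes all contaminants", {
  design <- mock_design()
  clean <- simulate_mock(design, contaminant_max_rel = 0, seed = 3)
  expect_equal(calibrate_floor(clean$counts, design)$recommended_floor, 0)
  sim <- simulate_mock(design, contaminant_max_rel = 0.0015, seed = 3)
  cal <- calibrate_floor(sim$counts, design)
  expect_lte(cal$recommended_floor, 0.002)
  rel <- to_relative_abundance(sim$counts)
  flo <- apply_abundance_floor(rel, 0.002)$rel
  contam_cols <- setdiff(colnames(rel), design$member_ids)
  expect_true(all(flo[, contam_cols] == 0))
  # a contaminant above the default floor is flagged as not removed
  boosted <- sim$counts
  boosted[1, contam_cols[1]] <- as.integer(0.004 * sum(boosted[1, ]) / (1 - 0.004)) + 1L
  cal2 <- calibrate_floor(boosted, design)
  expect_gt(cal2$recommended_floor, 0.002)
  expect_false(cal2$report$removed_by_default_floor[
    cal2$report$feature_id == contam_cols[1]])
  bogus <- matrix(1L, 1, 1, dimnames = list("s1", "unrelated"))
  expect_error(calibrate_floor(bogus, design), "overlap")
})
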