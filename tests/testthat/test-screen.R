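# compact hand-built scan/profile fixtures for the screen logic
mk_scan <- function(...) {
  df <- rbind(...)
  df$df <- 1L; df$n_used <- 100L; df$effects <- ""
  df$degenerate <- FALSE; df$threshold <- 0.001
  df$qq_deviates <- df$significant
  class(df) <- c("association_scan", "data.frame")
  df
}
scan_row <- function(feature, trait, env, p, significant) {
  data.frame(feature = feature, trait = trait, env = env, p = p,
             significant = significant, stringsAsFactors = FALSE)
}

test_that("class profiles report means, frequencies and differences", {
  G <- make_ld_panel(n_group1 = 6, n_group2 = 4, seed = 2)
  map <- make_map(G)
  bl <- find_blocks(G, map)
  b <- bl[[1]]
  traits <- trait_table(data.frame(
    line = rep(line_ids(G), 2),
    trait = "gy",
    env = rep(c("heat", "irrigated"), each = nrow(G$calls)),
    value = c(rep(c(10, 20), c(6, 4)), rep(5, 10))))
  pr <- class_profiles(bl, G, traits)
  expect_true(all(pr$block == b$name))
  heat <- pr[pr$env == "heat", ]
  expect_equal(sum(unique(heat[, c("class", "freq_pct")])$freq_pct), 100)
  minor <- heat[heat$freq_pct < 50, ]
  expect_equal(minor$mean, 20)
  expect_equal(minor$diff_vs_best_other, 10)
  # identical trait values in irrigated: zero difference everywhere
  irr <- pr[pr$env == "irrigated", ]
  expect_true(all(irr$diff_vs_best_other == 0))
  # frequencies recomputed from assignments match the block exactly
  expect_equal(sort(unique(heat$freq_pct)) / 100,
               sort(unname(assign_classes(b, G)$class_freq)))
  expect_error(class_profiles(list(list(name = "x", markers = "nope")),
                              G, traits), "absent")
})

test_that("the screen applies rarity, significance, confounder and penalty rules", {
  G <- make_ld_panel(n_group1 = 85, n_group2 = 15, seed = 3)
  map <- make_map(G)
  bl <- find_blocks(G, map)
  b <- bl[[1]]
  set.seed(4)
  n <- nrow(G$calls)
  rare <- c(rep(FALSE, 85), rep(TRUE, 15))
  traits <- trait_table(rbind(
    data.frame(line = line_ids(G), trait = "gy", env = "heat",
               value = 100 + 50 * rare + rnorm(n, 0, 5)),
    data.frame(line = line_ids(G), trait = "gy", env = "irrigated",
               value = 200 + rnorm(n, 0, 5)),
    data.frame(line = line_ids(G), trait = "days_to_heading", env = "heat",
               value = 80 + rnorm(n))))
  pr <- class_profiles(bl, G, traits)
  sc_ok <- mk_scan(scan_row(b$name, "gy", "heat", 1e-6, TRUE),
                   scan_row(b$name, "gy", "irrigated", 0.5, FALSE),
                   scan_row(b$name, "days_to_heading", "heat", 0.4, FALSE))
  out <- screen_rare_favorable(pr, sc_ok, traits, "gy")
  expect_identical(nrow(out), 1L)
  expect_equal(out$freq_pct, 15)
  expect_identical(out$favorable_envs, "heat")
  expect_true(out$n_favorable == 1L)
  # confounder association disqualifies the same block
  sc_conf <- mk_scan(scan_row(b$name, "gy", "heat", 1e-6, TRUE),
                     scan_row(b$name, "days_to_heading", "heat", 1e-5, TRUE))
  expect_identical(nrow(screen_rare_favorable(pr, sc_conf, traits, "gy")), 0L)
  # missing confounder scan is an error
  sc_noconf <- mk_scan(scan_row(b$name, "gy", "heat", 1e-6, TRUE))
  expect_error(screen_rare_favorable(pr, sc_noconf, traits, "gy"),
               "days_to_heading")
  # empty scan results produce an empty candidate list
  sc_empty <- mk_scan(scan_row(b$name, "days_to_heading", "heat", 0.4, FALSE))
  expect_identical(nrow(screen_rare_favorable(pr, sc_empty, traits, "gy")), 0L)
  # subset property: candidates are always scan-significant blocks
  expect_true(all(out$block %in% sc_ok$feature[sc_ok$significant]))
})

test_that("a real trait penalty suppresses the candidate", {
  G <- make_ld_panel(n_group1 = 85, n_group2 = 15, seed = 6)
  map <- make_map(G)
  bl <- find_blocks(G, map)
  b <- bl[[1]]
  set.seed(7)
  n <- nrow(G$calls)
  rare <- c(rep(FALSE, 85), rep(TRUE, 15))
  traits <- trait_table(rbind(
    data.frame(line = line_ids(G), trait = "gy", env = "heat",
               value = 100 + 50 * rare + rnorm(n, 0, 5)),
    data.frame(line = line_ids(G), trait = "gy", env = "irrigated",
               value = 200 - 60 * rare + rnorm(n, 0, 5)),
    data.frame(line = line_ids(G), trait = "days_to_heading", env = "heat",
               value = 80 + rnorm(n))))
  pr <- class_profiles(bl, G, traits)
  sc <- mk_scan(scan_row(b$name, "gy", "heat", 1e-6, TRUE),
                scan_row(b$name, "days_to_heading", "heat", 0.4, FALSE))
  expect_identical(nrow(screen_rare_favorable(pr, sc, traits, "gy")), 0L)
})

test_that("dropping the confounder check never shrinks the candidate set", {
  rep_cand <- function(seed) {
    G <- make_ld_panel(n_group1 = 85, n_group2 = 15, seed = seed)
    map <- make_map(G)
    bl <- find_blocks(G, map)
    b <- bl[[1]]
    set.seed(seed + 100)
    n <- nrow(G$calls)
    rare <- c(rep(FALSE, 85), rep(TRUE, 15))
    traits <- trait_table(rbind(
      data.frame(line = line_ids(G), trait = "gy", env = "heat",
                 value = 100 + 40 * rare + rnorm(n, 0, 8)),
      data.frame(line = line_ids(G), trait = "days_to_heading", env = "heat",
                 value = 80 + rnorm(n))))
    pr <- class_profiles(bl, G, traits)
    # confounder randomly significant or not
    sc <- mk_scan(scan_row(b$name, "gy", "heat", 1e-6, TRUE),
                  scan_row(b$name, "days_to_heading", "heat",
                           ifelse(seed %% 2, 1e-5, 0.5), seed %% 2 == 1))
    with_conf <- nrow(screen_rare_favorable(pr, sc, traits, "gy"))
    # disable the check by pointing it at an always-null pseudo-trait
    sc2 <- rbind(sc, mk_scan(scan_row(b$name, "none", "heat", 1, FALSE)))
    class(sc2) <- class(sc)
    without_conf <- nrow(screen_rare_favorable(pr, sc2, traits, "gy",
                                               confounder_trait = "none"))
    c(with_conf, without_conf)
  }
  for (s in 1:4) {
    r <- rep_cand(s)
    expect_gte(r[2], r[1])
  }
})

test_that("consistency matrix counts significant instances per feature", {
  sc <- mk_scan(scan_row("HB1.1", "gy", "heat", 1e-6, TRUE),
                scan_row("HB1.1", "gy", "irrigated", 1e-4, TRUE),
                scan_row("HB1.1", "biomass", "heat", 0.2, FALSE),
                scan_row("HB2.3", "gy", "heat", 0.9, FALSE))
  cm <- consistency_matrix(sc)
  expect_identical(dim(cm$matrix), c(2L, 3L))
  expect_identical(unname(cm$row_sums["HB1.1"]), 2)
  expect_identical(unname(cm$row_sums["HB2.3"]), 0)
  # all-blank matrix when nothing is significant
  sc0 <- mk_scan(scan_row("HB1.1", "gy", "heat", 0.9, FALSE))
  cm0 <- consistency_matrix(sc0)
  expect_identical(sum(cm0$matrix), 0L)
  expect_error(consistency_matrix(sc[0, ]), "empty")
})
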