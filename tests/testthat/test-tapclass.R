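make_pooled <- function(...) {
  # families described as list(name = c(dev, stim, both, none)) gene counts
  specs <- list(...)
  purrr::imap(specs, function(cnt, fam) {
    tibble::tibble(
      tap_family = fam,
      process_class = rep(c("developmental", "stimulus_stress", "both", "none"),
                          cnt))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(gene_id = sprintf("g%04d", dplyr::row_number()),
                  species = "A")
}

test_that("combining species tables derives process classes from GO sides", {
  tap_a <- tibble::tibble(gene_id = c("a1", "a2", "a3"), species = "A",
                          tap_family = "fam1")
  tap_b <- tibble::tibble(gene_id = c("b1", "b2"), species = "B",
                          tap_family = c("fam1", "fam2"))
  classes <- tibble::tibble(
    gene_id = c("a1", "a2", "a2", "b1", "b1"),
    class = c("developmental", "developmental", "stress", "stimulus",
              "stress"))
  pooled <- combine_tap_annotations(tap_a, tap_b, classes)
  get <- function(g) pooled$process_class[pooled$gene_id == g]
  expect_equal(get("a1"), "developmental")
  expect_equal(get("a2"), "both")
  expect_equal(get("b1"), "stimulus_stress")
  expect_equal(get("a3"), "none")  # unannotated stays in the table
  # per-species counts preserved by pooling
  expect_equal(sum(pooled$species == "A"), 3)
  expect_equal(sum(pooled$species == "B"), 2)
  # one family per gene within a species
  tap_dup <- tibble::tibble(gene_id = c("a1", "a1"), species = "A",
                            tap_family = c("fam1", "fam2"))
  expect_error(combine_tap_annotations(tap_dup, tap_b, classes),
               "more than one family")
  expect_error(combine_tap_annotations(
    tap_a, tap_b, tibble::tibble(gene_id = "a1", class = "weird")),
    "unknown process class")
})

test_that("a fully specialized family reaches quality class 1", {
  pooled <- make_pooled(focal = c(0, 20, 0, 0),
                        bg = c(50, 50, 0, 0))
  cls <- classify_tap_families(pooled)
  focal <- cls[cls$tap_family == "focal", ]
  expect_equal(focal$assigned_class, "stimulus_stress")
  expect_equal(focal$quality_class, 1L)
  # raw p matches the one-sided hypergeometric on (20, 0 | 50, 50)
  expect_equal(focal$p,
               stats::fisher.test(matrix(c(20, 50, 0, 50), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-10)
  # BH spans all four family x class tests of the run
  raw <- cryomoss:::tap_family_tests(pooled)$tests$p
  expect_equal(sort(unique(cls$p_bh)),
               sort(unique(bh_adjust(raw)[match(
                 paste(cls$tap_family, cls$assigned_class),
                 paste(cryomoss:::tap_family_tests(pooled)$tests$tap_family,
                       cryomoss:::tap_family_tests(pooled)$tests$class))])))
})

test_that("a family mirroring the background is quality 3 by majority", {
  pooled <- make_pooled(focal = c(4, 6, 0, 0),
                        bg1 = c(40, 60, 0, 0),
                        bg2 = c(20, 30, 0, 0))
  cls <- classify_tap_families(pooled)
  focal <- cls[cls$tap_family == "focal", ]
  expect_equal(focal$quality_class, 3L)
  expect_equal(focal$assigned_class, "stimulus_stress")
  expect_equal(focal$flag, "stimulus_stress")
})

test_that("tied counts without significance are unspecialized", {
  pooled <- make_pooled(tied = c(5, 5, 0, 0),
                        bg = c(30, 30, 0, 5))
  cls <- classify_tap_families(pooled)
  tied <- cls[cls$tap_family == "tied", ]
  expect_equal(tied$quality_class, 3L)
  expect_equal(tied$flag, "unspecialized")
  expect_true(is.na(tied$assigned_class))
})

test_that("'both' genes count toward each side of the tabulation", {
  pooled <- make_pooled(f1 = c(2, 3, 4, 1), f2 = c(10, 10, 0, 0))
  cls <- classify_tap_families(pooled)
  f1 <- cls[cls$tap_family == "f1", ]
  expect_equal(f1$n_annotated, 9L)
  expect_equal(f1$n_developmental, 6L)    # 2 dev + 4 both
  expect_equal(f1$n_stimulus_stress, 7L)  # 3 stim + 4 both
  expect_equal(f1$n_total, 10L)
})

test_that("classification is invariant to gene order and species swaps", {
  tabs <- simulate_tap_tables(n_stress = 6, n_dev = 4, n_neutral = 2,
                              family_size = 14, seed = 31)
  pooled <- combine_tap_annotations(
    tabs$tap[tabs$tap$species == "Ppatens", ],
    tabs$tap[tabs$tap$species == "Athaliana", ], tabs$classes)
  base <- classify_tap_families(pooled)
  shuffled <- pooled[sample.int(nrow(pooled)), ]
  swapped <- dplyr::mutate(shuffled,
                           species = ifelse(.data$species == "Ppatens",
                                            "Athaliana", "Ppatens"))
  expect_equal(tibble::as_tibble(classify_tap_families(shuffled)),
               tibble::as_tibble(base))
  expect_equal(tibble::as_tibble(classify_tap_families(swapped)),
               tibble::as_tibble(base))
})

test_that("identical family compositions yield no significant classifications", {
  pooled <- make_pooled(f1 = c(6, 9, 1, 2), f2 = c(6, 9, 1, 2),
                        f3 = c(6, 9, 1, 2), f4 = c(6, 9, 1, 2))
  cls <- classify_tap_families(pooled)
  expect_true(all(cls$quality_class == 3L))
  expect_true(all(cls$flag == "stimulus_stress"))
})

test_that("classify_family reports a single family from the full run", {
  pooled <- make_pooled(focal = c(0, 15, 0, 0), bg = c(40, 40, 0, 0))
  one <- classify_family(pooled, "focal")
  full <- classify_tap_families(pooled)
  expect_equal(tibble::as_tibble(one),
               tibble::as_tibble(full[full$tap_family == "focal", ]))
  expect_error(classify_family(pooled, "ghost"), "empty or absent")
})

test_that("a planted specialization partition is recovered", {
  tabs <- simulate_tap_tables(n_stress = 10, n_dev = 5, n_neutral = 2,
                              family_size = 20, class_bias = 0.9, seed = 53)
  pooled <- combine_tap_annotations(
    tabs$tap[tabs$tap$species == "Ppatens", ],
    tabs$tap[tabs$tap$species == "Athaliana", ], tabs$classes)
  cls <- classify_tap_families(pooled)
  merged <- dplyr::inner_join(tibble::as_tibble(cls), tabs$truth,
                              by = "tap_family")
  biased <- merged[merged$planted_class != "none", ]
  expect_gte(mean(biased$assigned_class == biased$planted_class,
                  na.rm = TRUE), 0.9)
})

test_that("glance summarizes family counts per specialization", {
  tabs <- simulate_tap_tables(n_stress = 5, n_dev = 3, n_neutral = 1,
                              family_size = 12, seed = 2)
  pooled <- combine_tap_annotations(
    tabs$tap[tabs$tap$species == "Ppatens", ],
    tabs$tap[tabs$tap$species == "Athaliana", ], tabs$classes)
  cls <- classify_tap_families(pooled)
  gl <- glance(cls)
  expect_equal(gl$n_families, 9L)
  expect_equal(gl$n_stimulus_stress + gl$n_developmental + gl$n_unspecialized,
               9L)
  expect_equal(gl$n_quality1 + gl$n_quality2 + gl$n_quality3, 9L)
})
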