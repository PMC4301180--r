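# shared fixtures; everything is generated in code, cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_sim <- function() {
  cached("small_sim", function() {
    simulate_experiment(sim_config(n_genes = 800, seed = 101))
  })
}

small_deg <- function() {
  cached("small_deg", function() call_degs(small_sim()))
}

# build a cryomoss_deg object from explicit per-pair calls; `calls` needs
# gene_id, t_later, deg, fold_change (control comparisons only)
fake_deg <- function(calls, time_points = c(0, 1, 3, 8, 24)) {
  control <- time_points[1]
  grid <- tidyr::expand_grid(gene_id = unique(calls$gene_id),
                             t_later = setdiff(time_points, control))
  pairs <- dplyr::left_join(grid, calls, by = c("gene_id", "t_later")) |>
    dplyr::mutate(
      deg = !is.na(deg) & deg,
      fold_change = ifelse(is.na(fold_change), 1, fold_change),
      t_earlier = control,
      pair = sprintf("%g h/%g h", t_earlier, t_later),
      tukey_p = ifelse(deg, 1e-4, 0.9),
      tukey_p_bonf = pmin(1, tukey_p * 10),
      tested = TRUE,
      direction = dplyr::case_when(deg & fold_change > 1 ~ "induced",
                                   deg & fold_change < 1 ~ "repressed",
                                   TRUE ~ "none"))
  genes <- dplyr::distinct(pairs, gene_id) |>
    dplyr::mutate(f = 1, p = 0.01, p_bh = 0.01, gate = TRUE)
  structure(list(genes = genes, pairs = pairs, time_points = time_points,
                 control = control, alpha = 0.05, alpha_pair = 0.05,
                 n_pairs = choose(length(time_points), 2)),
            class = "cryomoss_deg")
}

# annotation table with a given orphan pattern
fake_annotation <- function(gene_id, orphan) {
  tibble::tibble(gene_id = gene_id, orphan = orphan,
                 tap_family = NA_character_)
}

# independent literal implementation of the BH step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- rep(NA_real_, m)
  sorted <- p[ord]
  adj <- rev(cummin(rev(sorted * m / seq_len(m))))
  q[ord] <- pmin(1, adj)
  q
}

# literal hypergeometric enumeration oracle for a 2x2 table using choose()
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  xs <- lo:hi
  dens <- choose(m, xs) * choose(n_, k - xs) / choose(m + n_, k)
  d_obs <- dens[xs == a]
  list(p_two_sided = min(1, sum(dens[dens <= d_obs * (1 + 1e-7)])),
       p_over = min(1, sum(dens[xs >= a])),
       p_under = min(1, sum(dens[xs <= a])))
}
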