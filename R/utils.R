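# internal validators shared across modules

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_probabilities <- function(p, name = "p") {
  if (!is.numeric(p)) abort(sprintf("`%s` must be numeric.", name))
  if (anyNA(p)) abort(sprintf("`%s` must not contain missing values.", name))
  if (any(p < 0 | p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]; offending values: %s.",
                  name, paste(format(p[p < 0 | p > 1][1:min(3, sum(p < 0 | p > 1))]),
                              collapse = ", ")))
  }
  invisible(p)
}

# coerce a wide expression tibble (gene_id + one column per sample) or a
# matrix with rownames into a numeric matrix with gene rownames
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) abort("expression matrix must have gene ids as rownames.")
    storage.mode(expr) <- "double"
    return(expr)
  }
  if (!is.data.frame(expr)) abort("`expr` must be a data frame or matrix.")
  if (!"gene_id" %in% names(expr)) abort("`expr` must contain a `gene_id` column.")
  ids <- as.character(expr$gene_id)
  if (anyDuplicated(ids)) abort("`gene_id` values must be unique.")
  mat <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

check_design <- function(design, samples = NULL) {
  if (!is.data.frame(design)) abort("`design` must be a data frame.")
  need <- c("sample_id", "time_point", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) abort(paste0("`design` is missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(design$sample_id)) abort("`design$sample_id` must be unique.")
  if (anyDuplicated(design[c("time_point", "replicate")])) {
    abort("each (time_point, replicate) pair may occur only once in `design`.")
  }
  if (!is.null(samples)) {
    miss <- setdiff(design$sample_id, samples)
    if (length(miss)) abort(paste0("design samples absent from matrix: ", paste(miss, collapse = ", ")))
  }
  invisible(design)
}

pair_label <- function(earlier, later) sprintf("%g h/%g h", earlier, later)

# round half away from zero at `digits` decimals (printed-percentage convention)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
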