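# shared fixtures, all built in code

# independent day-set classifier used as the oracle for allen_classify():
# relations are decided from the covered-day sets and their extrema, not
# from the endpoint comparisons the implementation uses
oracle_label <- function(xs, xe, ys, ye) {
  X <- xs:(xe - 1)
  Y <- ys:(ye - 1)
  if (identical(X, Y)) {
    "equals"
  } else if (max(X) < min(Y) - 1) {
    "before"
  } else if (max(X) == min(Y) - 1) {
    "meets"
  } else if (max(Y) < min(X) - 1) {
    "after"
  } else if (max(Y) == min(X) - 1) {
    "met_by"
  } else if (min(X) == min(Y)) {
    if (max(X) < max(Y)) "starts" else "started_by"
  } else if (max(X) == max(Y)) {
    if (min(X) > min(Y)) "finishes" else "finished_by"
  } else if (all(Y %in% X)) {
    "contains"
  } else if (all(X %in% Y)) {
    "during"
  } else if (min(X) < min(Y)) {
    "overlaps"
  } else {
    "overlapped_by"
  }
}

# all ordered pairs of non-degenerate intervals with endpoints in 0..grid
interval_pair_grid <- function(grid = 6L) {
  iv <- expand.grid(s = 0:grid, e = 0:grid)
  iv <- iv[iv$e > iv$s, ]
  pairs <- expand.grid(i = seq_len(nrow(iv)), j = seq_len(nrow(iv)))
  data.frame(
    xs = iv$s[pairs$i], xe = iv$e[pairs$i],
    ys = iv$s[pairs$j], ye = iv$e[pairs$j]
  )
}

write_disp_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(
    c("person_id,din,date_of_service,days_supply,quantity,strength", rows),
    path
  )
  path
}

# a mixture tibble restricted to continuity-only relations (before/meets),
# the regime in which cleaned data carry no coverage overruns
continuity_mixture <- function() {
  mx <- oat_relation_mixtures()
  mx$prob <- ifelse(mx$relation %in% c("before", "meets"), mx$prob, 0)
  stats::ave(mx$prob, mx$drug, FUN = function(p) p / sum(p)) -> mx$prob
  mx
}

total_mg <- function(d) sum(d$quantity * d$strength)

segment_mg <- function(ep) {
  sum(vapply(ep$dose_segments, function(s) {
    if (is.null(s) || nrow(s) == 0) 0 else sum((s$end - s$start) * s$dose)
  }, numeric(1)))
}
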