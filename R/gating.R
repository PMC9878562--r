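# Four-gate behavioral classification on the (arrest, directionality) plane.
#
# The four gates tile [0,1]^2:
#   low A,  low Gamma  -> chemokinesis  (stimulated but undirected movement)
#   high A, low Gamma  -> immobile
#   high A, high Gamma -> polarized     (visibly polarized, little migration)
#   low A,  high Gamma -> directional   (pronounced directional migration)
# "High" means >= threshold on both axes (a fixed, documented convention).

GATE_LEVELS <- c("chemokinesis", "immobile", "polarized", "directional")

#' Gate thresholds and sampling parameters
#'
#' @param a_star Arrest-coefficient threshold in (0, 1) separating low from
#'   high arrest. Default 0.6.
#' @param d_star Directionality threshold in (0, 1). Default 0.5.
#' @param sample_N Tracklets sampled per group before counting
#'   (default 1000).
#' @param seed Integer seed for the sampling; the same seed gives identical
#'   samples regardless of input row order.
#' @param allow_short_groups If `TRUE`, groups smaller than `sample_N` are
#'   used in full (with a message) instead of erroring.
#' @return A `gate_config` list.
#' @export
gate_config <- function(a_star = 0.6, d_star = 0.5, sample_N = 1000L,
                        seed = 1L, allow_short_groups = FALSE) {
  if (!is_number(a_star) || a_star <= 0 || a_star >= 1) {
    stop_config("a_star must be strictly inside (0, 1)")
  }
  if (!is_number(d_star) || d_star <= 0 || d_star >= 1) {
    stop_config("d_star must be strictly inside (0, 1)")
  }
  sample_N <- as.integer(sample_N)
  if (is.na(sample_N) || sample_N < 1L) stop_config("sample_N must be >= 1")
  if (!is_number(seed)) stop_config("seed must be a single integer")
  if (!is_flag(allow_short_groups)) {
    stop_config("allow_short_groups must be TRUE/FALSE")
  }
  structure(list(a_star = a_star, d_star = d_star, sample_N = sample_N,
                 seed = as.integer(seed),
                 allow_short_groups = allow_short_groups),
            class = "gate_config")
}

#' Classify (arrest, directionality) pairs into the four gates
#'
#' Vectorized over `A` and `Gamma`. Values at or above a threshold count
#' as "high" on that axis, so every point of the unit square receives
#' exactly one label.
#'
#' @param A Arrest coefficients in \[0, 1\].
#' @param Gamma Directionality values in \[0, 1\].
#' @param cfg A [gate_config()].
#' @return A factor with levels `chemokinesis`, `immobile`, `polarized`,
#'   `directional`.
#' @export
classify_gate <- function(A, Gamma, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  high_a <- A >= cfg$a_star
  high_g <- Gamma >= cfg$d_star
  lab <- ifelse(high_a,
                ifelse(high_g, "polarized", "immobile"),
                ifelse(high_g, "directional", "chemokinesis"))
  factor(lab, levels = GATE_LEVELS)
}

#' Attach gate labels to a full tracklet-metrics table
#'
#' Unlike [gate_counts()] this labels every tracklet (no sampling); the
#' neighborhood module uses it to decide which leader tracklets count as
#' motile.
#'
#' @param metrics Output of [tracklet_metrics()].
#' @param cfg A [gate_config()].
#' @return `metrics` with an added `gate` factor column.
#' @export
classify_tracklets <- function(metrics, cfg = gate_config()) {
  metrics$gate <- classify_gate(metrics$A, metrics$Gamma, cfg)
  metrics
}

#' Per-group gate counts from seeded tracklet samples
#'
#' Per group, a uniform sample of `sample_N` tracklets is drawn without
#' replacement and classified; the four gate counts (which sum to the
#' sample size) are returned together with the sample itself and the
#' configuration. Sampling is platform-stable: tracklets are first sorted
#' by (`cell_id`, `start_frame`), then a seeded shuffle is applied, so the
#' same seed yields the same sample whatever the input row order. Groups
#' are processed in sorted name order.
#'
#' @param metrics Output of [tracklet_metrics()] covering one or more
#'   groups.
#' @param cfg A [gate_config()].
#' @return A `gate_assignment` list with elements `counts` (tibble group x
#'   gate x n), `sample` (one row per sampled tracklet, incl. `gate`) and
#'   `config`.
#' @export
gate_counts <- function(metrics, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  groups <- sort(unique(metrics$group), method = "radix")
  samples <- with_preserved_seed(cfg$seed, {
    lapply(groups, function(g) {
      sub <- metrics[metrics$group == g, , drop = FALSE]
      sub <- sub[order(sub$cell_id, sub$start_frame, method = "radix"), ,
                 drop = FALSE]
      n <- nrow(sub)
      if (n < cfg$sample_N) {
        if (!cfg$allow_short_groups) {
          stop_validation(paste0("group '", g, "' has only ", n,
                                 " tracklets but sample_N = ", cfg$sample_N))
        }
        message("gate_counts: group '", g, "' short by ",
                cfg$sample_N - n, " tracklets; using all ", n)
      }
      take <- head(sample.int(n), min(n, cfg$sample_N))
      sub[take, , drop = FALSE]
    })
  })
  sample_tbl <- bind_rows(samples)
  if (nrow(sample_tbl) == 0) {
    sample_tbl <- metrics[0, , drop = FALSE]
    sample_tbl$gate <- factor(character(0), levels = GATE_LEVELS)
    counts <- tibble(group = character(0),
                     gate = factor(character(0), levels = GATE_LEVELS),
                     n = integer(0))
    return(structure(list(counts = counts, sample = sample_tbl,
                          config = cfg),
                     class = "gate_assignment"))
  }
  sample_tbl$gate <- classify_gate(sample_tbl$A, sample_tbl$Gamma, cfg)
  counts <- as.data.frame(table(group = sample_tbl$group,
                                gate = sample_tbl$gate),
                          responseName = "n")
  counts <- as_tibble(counts)
  counts$group <- as.character(counts$group)
  counts <- counts[order(counts$group, counts$gate), , drop = FALSE]
  structure(list(counts = counts, sample = sample_tbl, config = cfg),
            class = "gate_assignment")
}

#' @export
print.gate_assignment <- function(x, ...) {
  cat("Gate assignment (a* =", x$config$a_star, ", d* =", x$config$d_star,
      ", N =", x$config$sample_N, ", seed =", x$config$seed, ")\n")
  m <- gate_count_matrix(x)
  print(m)
  invisible(x)
}

#' Gate counts as a group x gate matrix
#'
#' @param assignment A `gate_assignment` from [gate_counts()].
#' @return An integer matrix with one row per group and one column per
#'   gate.
#' @export
gate_count_matrix <- function(assignment) {
  counts <- assignment$counts
  groups <- sort(unique(counts$group), method = "radix")
  m <- matrix(0L, nrow = length(groups), ncol = length(GATE_LEVELS),
              dimnames = list(groups, GATE_LEVELS))
  for (i in seq_len(nrow(counts))) {
    m[counts$group[i], as.character(counts$gate[i])] <- counts$n[i]
  }
  m
}

#' Scatter-plot export of a gate assignment
#'
#' One row per sampled tracklet with its coordinates on the
#' (arrest, directionality) plane and its gate -- the machine-readable twin
#' of a gated scatter plot.
#'
#' @param assignment A `gate_assignment` from [gate_counts()].
#' @return A tibble with `tracklet_id`, `cell_id`, `group`, `A`, `Gamma`,
#'   `gate`.
#' @export
gate_scatter_export <- function(assignment) {
  s <- assignment$sample
  s[, c("tracklet_id", "cell_id", "group", "A", "Gamma", "gate")]
}

#' Chi-square comparison of two gate-count profiles
#'
#' Compares the four gate counts of one group against another (e.g. a
#' perturbed mixture against the follower-alone arm). Gates empty in both
#' profiles are dropped; if at most one populated gate remains the
#' profiles are identical by construction and p = 1.
#'
#' @param counts_a,counts_b Named integer vectors of gate counts (names
#'   from the four gate labels), e.g. rows of [gate_count_matrix()].
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
compare_gate_profiles <- function(counts_a, counts_b) {
  m <- rbind(counts_a[GATE_LEVELS], counts_b[GATE_LEVELS])
  m[is.na(m)] <- 0
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
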