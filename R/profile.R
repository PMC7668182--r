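#' Seed-by-network connectivity profile table
#'
#' For every subject, the mean Pearson correlation over all (seed vertex,
#' network vertex) pairs, for each of the 8 cells of the design: seed
#' hemisphere (L/R) x network (DMN/ExN) x network hemisphere (L/R). This is
#' the long table behind the connectivity spider plot and the three-factor
#' ANOVA.
#'
#' @param rest list, one element per subject, each a list with `left` and
#'   `right` T x V time-series matrices (as in an `asym_cohort`'s `rest`).
#' @param fa_left,fa_right seed vertex indices on the left / right hemisphere
#'   (e.g. the FA cluster and its homologue).
#' @param networks named list with masks `dmn_left`, `dmn_right`, `exn_left`,
#'   `exn_right` (hemisphere-local indices). A network mask sharing vertices
#'   with the same-hemisphere seed is an error; an empty mask flags its cells
#'   as missing (`NA`).
#' @return A [tibble::tibble()] with columns `subject`, `seed_hemisphere`,
#'   `network`, `network_hemisphere`, `mean_connectivity`.
#' @export
build_profile_table <- function(rest, fa_left, fa_right, networks) {
  need <- c("dmn_left", "dmn_right", "exn_left", "exn_right")
  if (!all(need %in% names(networks))) {
    stop("networks must contain masks: ", paste(need, collapse = ", "))
  }
  if (length(fa_left) == 0L || length(fa_right) == 0L) stop("empty seed mask")
  overlap <- c(intersect(networks$dmn_left, fa_left),
               intersect(networks$exn_left, fa_left),
               intersect(networks$dmn_right, fa_right),
               intersect(networks$exn_right, fa_right))
  if (length(overlap) > 0) stop("network masks must be disjoint from the seeds")

  cells <- expand.grid(seed_hemisphere = c("L", "R"), network = c("DMN", "ExN"),
                       network_hemisphere = c("L", "R"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_along(rest), function(s) {
    ts <- rest[[s]]
    val <- vapply(seq_len(nrow(cells)), function(i) {
      seeds <- if (cells$seed_hemisphere[i] == "L") fa_left else fa_right
      seed_ts <- if (cells$seed_hemisphere[i] == "L") ts$left else ts$right
      net_name <- paste0(tolower(cells$network[i]),
                         if (cells$network_hemisphere[i] == "L") "_left" else "_right")
      net <- networks[[net_name]]
      if (length(net) == 0L) return(NA_real_)
      net_ts <- if (cells$network_hemisphere[i] == "L") ts$left else ts$right
      mean(stats::cor(seed_ts[, seeds, drop = FALSE], net_ts[, net, drop = FALSE]))
    }, numeric(1))
    tibble::tibble(subject = s, cells, mean_connectivity = val)
  })
  do.call(rbind, rows)
}

#' Three-factor fixed-effects ANOVA of the connectivity profile
#'
#' Fixed-effects 2 x 2 x 2 ANOVA on the long profile table (observations =
#' subject-cells): sums of squares, F and p for the 3 main effects, 3 two-way
#' interactions and the three-way interaction, against the residual error.
#' The seed-by-network interaction is the effect of interest: it captures a
#' seed-hemisphere difference that is specific to one network.
#'
#' @param table a profile table from [build_profile_table()].
#' @return An `asym_anova`: list with `effects` (tibble: `effect`, `df_num`,
#'   `df_den`, `sum_sq`, `F`, `p`), `residual_ss`, `n_obs`.
#' @export
three_way_anova <- function(table) {
  tab <- as.data.frame(table)
  tab <- tab[stats::complete.cases(tab[, c("seed_hemisphere", "network",
                                           "network_hemisphere",
                                           "mean_connectivity")]), ]
  counts <- stats::xtabs(~ seed_hemisphere + network + network_hemisphere, data = tab)
  if (any(counts == 0)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    stop("incomplete design; missing cell(s): ",
         paste(apply(miss, 1, function(i)
           paste(dimnames(counts)[[1]][i[1]], dimnames(counts)[[2]][i[2]],
                 dimnames(counts)[[3]][i[3]], sep = ":")), collapse = ", "))
  }
  if (length(unique(tab$subject)) < 2L) stop("need at least 2 subjects")
  tab$seed_hemisphere <- factor(tab$seed_hemisphere)
  tab$network <- factor(tab$network)
  tab$network_hemisphere <- factor(tab$network_hemisphere)
  fit <- stats::aov(mean_connectivity ~ seed_hemisphere * network * network_hemisphere,
                    data = tab)
  sm <- summary(fit)[[1]]
  eff_names <- trimws(rownames(sm))
  resid_row <- eff_names == "Residuals"
  df_den <- sm$Df[resid_row]
  sse <- sm$`Sum Sq`[resid_row]
  eff <- tibble::tibble(
    effect = eff_names[!resid_row],
    df_num = sm$Df[!resid_row],
    df_den = df_den,
    sum_sq = sm$`Sum Sq`[!resid_row],
    F = sm$`F value`[!resid_row],
    p = sm$`Pr(>F)`[!resid_row]
  )
  # guard the degenerate zero-residual case: effects whose SS is numerically
  # zero (relative to the response scale) get F = 0, p = 1; genuinely nonzero
  # effects against a zero residual get infinite F
  if (sse <= 1e-12 * sum(tab$mean_connectivity^2)) {
    zero <- eff$sum_sq <= 1e-12 * sum(tab$mean_connectivity^2)
    eff$F <- ifelse(zero, 0, Inf)
    eff$p <- ifelse(zero, 1, 0)
  }
  structure(list(effects = eff, residual_ss = sse, n_obs = nrow(tab)),
            class = "asym_anova")
}

#' @export
print.asym_anova <- function(x, ...) {
  cat("three-factor ANOVA on", x$n_obs, "subject-cells\n")
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' Post hoc seed-hemisphere contrasts within networks
#'
#' For each requested network, the per-subject difference between the right-
#' and left-seed cells (averaged over network hemisphere) is tested with a
#' paired (one-sample) t test, and the p-values receive a single-step Sidak
#' family-wise adjustment over the requested family, so adjusted p >= raw p.
#'
#' @param table a profile table from [build_profile_table()].
#' @param networks networks to contrast (default both).
#' @return A [tibble::tibble()] with `contrast`, `estimate` (mean right-seed
#'   minus left-seed difference), `t`, `df`, `p`, `p_adj`.
#' @export
posthoc_contrasts <- function(table, networks = c("DMN", "ExN")) {
  tab <- as.data.frame(table)
  rows <- lapply(networks, function(net) {
    sub <- tab[tab$network == net, ]
    agg <- stats::aggregate(mean_connectivity ~ subject + seed_hemisphere,
                            data = sub, FUN = mean)
    wide <- merge(agg[agg$seed_hemisphere == "R", c("subject", "mean_connectivity")],
                  agg[agg$seed_hemisphere == "L", c("subject", "mean_connectivity")],
                  by = "subject", suffixes = c("_R", "_L"))
    d <- wide$mean_connectivity_R - wide$mean_connectivity_L
    if (length(d) < 2L) stop("need at least 2 subjects for contrasts")
    res <- group_onesample_t(d, 0)
    tibble::tibble(contrast = paste0("R_vs_L_seed_", net), estimate = mean(d),
                   t = res$t, df = res$df, p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, 1 - (1 - out$p)^nrow(out))
  out
}
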