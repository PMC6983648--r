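#' Timepoints with data from every animal
#'
#' Longitudinal analyses are restricted to timepoints where every animal in
#' the table has an aggregated value on both sides, so that early dropouts
#' cannot introduce survivorship bias.
#'
#' @param table Aggregated study table (one row per animal x day x side),
#'   with columns `animal`, `day`, `side` and a BF column (`aggregated_bf`
#'   or `bf`).
#' @return Character vector of complete day labels, in table order.
#' @export
complete_timepoints <- function(table) {
  bf <- table[[if ("aggregated_bf" %in% names(table)) "aggregated_bf" else "bf"]]
  ok <- !is.na(bf)
  n_animal <- length(unique(table$animal))
  days <- unique(table$day)
  keep <- vapply(days, function(d) {
    sub <- table[table$day == d & ok, ]
    nrow(sub) == 2 * n_animal &&
      length(unique(sub$animal)) == n_animal
  }, logical(1))
  as.character(days[keep])
}

# normalize an aggregated study table to factors used by the ANOVA,
# restricted to the analysis window (baseline through max_day_num) and to
# complete timepoints
anova_frame <- function(table, max_day_num = 15) {
  bf_col <- if ("aggregated_bf" %in% names(table)) "aggregated_bf" else "bf"
  need <- c("animal", "group", "day", "side", bf_col)
  if (!all(need %in% names(table)))
    stop("table must contain columns ", paste(need, collapse = ", "))
  if ("day_num" %in% names(table))
    table <- table[table$day_num <= max_day_num, ]
  key <- interaction(table$animal, table$day, table$side, drop = TRUE)
  if (any(tabulate(key) > 1))
    stop("more than one value per animal x day x side; ",
         "aggregate repeats first (see aggregate_measurements)")
  days <- complete_timepoints(table)
  if (length(days) < 2) stop("fewer than 2 complete timepoints")
  sub <- table[table$day %in% days, ]
  lev <- if ("day_num" %in% names(sub))
    unique(sub$day[order(sub$day_num)]) else days
  data.frame(animal = factor(sub$animal),
             group = factor(sub$group),
             day = factor(sub$day, levels = lev),
             side = factor(sub$side),
             bf = sub[[bf_col]])
}

#' Three-way repeated-measures ANOVA for longitudinal joint blood flow
#'
#' Mixed-design analysis with time and measurement side as within-subject
#' factors and group as the between-subjects factor, subjects nested in
#' groups. The sums of squares are decomposed into the four classical error
#' strata (subjects within groups; time x subjects; side x subjects;
#' time x side x subjects), which for this design reproduces the standard
#' univariate repeated-measures table even with unequal group sizes.
#' Analysis is automatically restricted to complete timepoints
#' ([complete_timepoints()]).
#'
#' Partial eta-squared for each effect is `SS_effect / (SS_effect +
#' SS_error)` with the error SS of that effect's stratum. Normality of the
#' response (Shapiro-Wilk) and sphericity of the multi-level within effects
#' (Mauchly) are attached.
#'
#' @param table Aggregated study table (see [aggregate_measurements()]).
#' @param max_day_num Upper end of the analysis window (numeric day); the
#'   longitudinal analysis covers baseline through day 15, before
#'   treatment starts and humane-endpoint dropout thins the groups.
#' @param check_assumptions Attach Shapiro-Wilk and Mauchly checks
#'   (disable inside large simulation loops).
#' @return Object of class `rm_anova`: `effects` data frame (effect, SS,
#'   df, MS, F, p, partial_eta_sq, error stratum, SS_error, df_error),
#'   `shapiro_p`, `mauchly` (list per within effect), `days_used`, `data`.
#' @export
rm_anova <- function(table, max_day_num = 15, check_assumptions = TRUE) {
  df <- anova_frame(table, max_day_num)
  fit <- stats::aov(bf ~ group * day * side + Error(animal / (day * side)),
                    data = df)
  sm <- summary(fit)

  strata <- list(
    `subjects within groups` = "Error: animal",
    `time x subjects within groups` = "Error: animal:day",
    `side x subjects within groups` = "Error: animal:side",
    `time x side x subjects within groups` = "Error: animal:day:side"
  )
  ss_scale <- sum(df$bf^2) + 1
  rows <- list()
  for (nm in names(strata)) {
    tab <- sm[[strata[[nm]]]][[1]]
    terms <- rownames(tab)
    err <- grepl("^Residuals", trimws(terms))
    ss_err <- sum(tab[err, "Sum Sq"])
    df_err <- sum(tab[err, "Df"])
    for (i in which(!err)) {
      ss <- tab[i, "Sum Sq"]
      dfe <- tab[i, "Df"]
      ms <- ss / dfe
      ms_err <- ss_err / df_err
      f <- if (ss_err > 1e-12 * ss_scale) ms / ms_err else NaN
      rows[[length(rows) + 1L]] <- data.frame(
        effect = trimws(terms[i]),
        SS = ss, df = dfe, MS = ms,
        F = f,
        p = if (is.finite(f)) stats::pf(f, dfe, df_err, lower.tail = FALSE)
        else NaN,
        partial_eta_sq = if (ss + ss_err > 1e-12 * ss_scale)
          ss / (ss + ss_err) else 0,
        error_stratum = nm, SS_error = ss_err, df_error = df_err,
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, rows)
  effects$effect <- sub("^group:day$", "day:group", effects$effect)
  rownames(effects) <- NULL

  mau <- if (check_assumptions) list(
    time = mauchly_sphericity(table, "time", max_day_num),
    side = mauchly_sphericity(table, "side", max_day_num),
    time_side = mauchly_sphericity(table, "time_side", max_day_num)
  ) else NULL
  structure(
    list(effects = effects,
         shapiro_p = if (check_assumptions && stats::sd(df$bf) > 0)
           stats::shapiro.test(df$bf)$p.value else NA_real_,
         mauchly = mau,
         days_used = levels(df$day),
         n_subjects = length(unique(df$animal)),
         data = df),
    class = "rm_anova"
  )
}

#' Mauchly's test of sphericity for a within-subject effect
#'
#' Tests whether the covariance matrix of the orthonormal contrasts of the
#' within effect is proportional to the identity, pooling residuals across
#' groups. A two-level effect is trivially spherical and returns p = 1 with
#' a note.
#'
#' @param table Aggregated study table.
#' @param effect One of `"time"`, `"side"`, `"time_side"`.
#' @param max_day_num Upper end of the analysis window (numeric day).
#' @return List with `W`, `p`, `df`, and `note`.
#' @export
mauchly_sphericity <- function(table, effect = c("time", "side", "time_side"),
                               max_day_num = 15) {
  effect <- match.arg(effect)
  df <- anova_frame(table, max_day_num)
  if (effect == "side" || (effect == "time" && nlevels(df$day) == 2)) {
    if (effect == "side")
      return(list(W = 1, p = 1, df = 0,
                  note = "2-level effect: sphericity trivially satisfied"))
  }
  # reshape needs a single within key
  df$cell <- interaction(df$day, df$side, sep = "_")
  wide <- stats::reshape(df[, c("animal", "group", "cell", "bf")],
                         idvar = c("animal", "group"), timevar = "cell",
                         direction = "wide", v.names = "bf")
  wide$group <- factor(wide$group)
  cells <- levels(df$cell)
  Y <- as.matrix(wide[, paste0("bf.", cells)])
  idata <- do.call(rbind, strsplit(cells, "_", fixed = TRUE))
  idata <- data.frame(day = factor(idata[, 1], levels = levels(df$day)),
                      side = factor(idata[, 2], levels = levels(df$side)))
  mlm <- if (nlevels(wide$group) > 1) stats::lm(Y ~ group, data = wide)
  else stats::lm(Y ~ 1, data = wide)
  mt <- switch(effect,
    time = stats::mauchly.test(mlm, M = ~day, X = ~1, idata = idata),
    time_side = stats::mauchly.test(mlm, M = ~day * side, X = ~day + side,
                                    idata = idata))
  list(W = unname(mt$statistic), p = mt$p.value,
       df = unname(mt$parameter), note = NULL)
}

#' Tukey HSD comparisons of the time means
#'
#' All pairwise comparisons of the timepoint means, pooled over sides and
#' groups (side showing no effect), using the time-stratum error mean
#' square of the side-averaged repeated-measures ANOVA and studentized-range
#' quantiles.
#'
#' @param table Aggregated study table.
#' @param alpha Familywise significance level.
#' @param max_day_num Upper end of the analysis window (numeric day).
#' @return Data frame with one row per timepoint pair: `day_a`, `day_b`,
#'   `diff`, `se`, `q`, `p_adj`, `significant`. Attributes `ms_error`,
#'   `df_error`, `means`.
#' @export
tukey_hsd_time <- function(table, alpha = 0.05, max_day_num = 15) {
  df <- anova_frame(table, max_day_num)
  # pool over sides: per-subject, per-day means
  pooled <- stats::aggregate(bf ~ animal + group + day, data = df, FUN = mean)
  fit <- if (nlevels(df$group) > 1)
    stats::aov(bf ~ group * day + Error(animal / day), data = pooled)
  else stats::aov(bf ~ day + Error(animal / day), data = pooled)
  tab <- summary(fit)[["Error: animal:day"]][[1]]
  err <- grepl("^Residuals", trimws(rownames(tab)))
  ms_e <- tab[err, "Mean Sq"]
  df_e <- tab[err, "Df"]
  n <- length(unique(pooled$animal))
  means <- tapply(pooled$bf, pooled$day, mean)
  k <- length(means)
  pairs <- utils::combn(names(means), 2)
  out <- data.frame(
    day_a = pairs[1, ], day_b = pairs[2, ],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    se = sqrt(2 * ms_e / n))
  out$q <- abs(out$diff) / sqrt(ms_e / n)
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_e, lower.tail = FALSE)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "ms_error") <- ms_e
  attr(out, "df_error") <- df_e
  attr(out, "means") <- means
  out
}

#' Average per-day correlation between blood flow and heart rate
#'
#' For each animal and timepoint with a full set of raw repeat measurements
#' (two sides x two repeats), the Pearson correlation between the four BF
#' values and their heart rates is computed; the coefficients are then
#' averaged over all animal-days. Only timepoints where every animal is
#' still on study contribute (no survivorship bias), and within those only
#' animal-days with all four raw values present (a lost repeat leaves too
#' few comparisons). Animal-days without variation in either variable are
#' skipped and logged.
#'
#' @param records Raw (unaggregated) study table with columns `animal`,
#'   `day`, `side`, `rep`, `bf`, `hr`.
#' @return List: `average_r`, `n_coefficients`, `per_day` (data frame of
#'   animal, day, r), `skipped` (count).
#' @export
hr_confound <- function(records) {
  stopifnot(all(c("animal", "day", "bf", "hr") %in% names(records)))
  ok <- !is.na(records$bf) & !is.na(records$hr)
  rec <- records[ok, ]
  n_animal <- length(unique(records$animal))
  cnt <- table(rec$animal, rec$day)
  all_on_study <- colnames(cnt)[colSums(cnt >= 1) == n_animal]
  rec <- rec[rec$day %in% all_on_study, ]
  full <- table(rec$animal, rec$day) == 4
  keep <- full[cbind(as.character(rec$animal), as.character(rec$day))]
  rec <- rec[keep, ]
  skipped <- 0L
  rows <- list()
  for (key in split(seq_len(nrow(rec)),
                    interaction(rec$animal, rec$day, drop = TRUE))) {
    r <- rec[key, ]
    if (stats::sd(r$bf) == 0 || stats::sd(r$hr) == 0) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      animal = r$animal[1], day = r$day[1], r = stats::cor(r$bf, r$hr))
  }
  per_day <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(), day = character(), r = numeric())
  if (skipped > 0)
    message(skipped, " animal-day(s) skipped (no variation)")
  list(average_r = if (nrow(per_day)) mean(per_day$r) else NA_real_,
       n_coefficients = nrow(per_day), per_day = per_day, skipped = skipped)
}

# Rand index between two partitions (fraction of concordant pairs)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' Hierarchical clustering of experimental-animal blood-flow time courses
#'
#' Ward's method on squared Euclidean distances between per-animal BF
#' feature vectors (side-averaged values over the complete-data window,
#' baseline through day 15 by default). The number of clusters is chosen by
#' the elbow of the within-cluster sum of squares (maximum second
#' difference, with a distance-to-chord fallback on ties), then confirmed
#' by k-means on the same features, and checked for stability under three
#' seeded row-order randomizations.
#'
#' @param table Aggregated study table.
#' @param k_max Largest cluster count considered (clipped to the number of
#'   animals).
#' @param max_day_num Upper end of the feature window (numeric day).
#' @param group Group whose animals are clustered.
#' @param seed Seed for k-means restarts and the stability shuffles.
#' @return List of class `cohort_clustering`: `k`, `partition` (named
#'   integer vector), `kmeans_partition`, `kmeans_agreement` (Rand index),
#'   `stable` (logical), `wss`, `hclust`, `features`.
#' @export
cohort_clustering <- function(table, k_max = 6L, max_day_num = 15,
                              group = "experimental", seed = 1L) {
  sub <- table[table$group == group, ]
  if ("day_num" %in% names(sub)) sub <- sub[sub$day_num <= max_day_num, ]
  bf_col <- if ("aggregated_bf" %in% names(sub)) "aggregated_bf" else "bf"
  pooled <- stats::aggregate(stats::setNames(sub[bf_col], "bf"),
                             by = sub[c("animal", "day")], FUN = mean)
  X <- stats::xtabs(bf ~ animal + day, data = pooled)
  X <- matrix(as.numeric(X), nrow(X), dimnames = dimnames(X))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 animals to cluster")
  k_max <- min(k_max, n)

  wss_for <- function(assign) {
    sum(unlist(lapply(split(seq_len(n), assign), function(ix) {
      xc <- X[ix, , drop = FALSE]
      sum(sweep(xc, 2, colMeans(xc))^2)
    })))
  }
  d2 <- stats::as.dist(as.matrix(stats::dist(X))^2)
  hc <- stats::hclust(d2, method = "ward.D")
  wss <- vapply(seq_len(k_max), function(k) wss_for(stats::cutree(hc, k)),
                numeric(1))

  tot <- wss[1]
  if (tot < 1e-12) {
    k_hat <- 1L
  } else if (k_max < 3) {
    k_hat <- k_max
  } else {
    d2nd <- diff(diff(wss))  # second difference at k = 2..k_max-1
    top <- which(d2nd > max(d2nd) - 1e-12 * tot)
    if (length(top) == 1L) {
      k_hat <- top[1] + 1L
    } else {
      # distance-to-chord fallback: point of the wss curve farthest from
      # the chord between k = 1 and k = k_max
      ks <- seq_len(k_max)
      chord <- wss[1] + (wss[k_max] - wss[1]) * (ks - 1) / (k_max - 1)
      k_hat <- which.max(chord - wss)
    }
  }
  part <- stats::cutree(hc, k_hat)

  set.seed(seed)
  km <- if (k_hat > 1)
    stats::kmeans(X, centers = k_hat, nstart = 25)$cluster
  else rep(1L, n)
  names(km) <- rownames(X)

  stable <- all(vapply(1:3, function(i) {
    set.seed(seed + i)
    perm <- sample(n)
    hp <- stats::hclust(stats::as.dist(as.matrix(stats::dist(X[perm, ]))^2),
                        method = "ward.D")
    pp <- stats::cutree(hp, k_hat)[order(perm)]
    rand_index(pp, part) == 1
  }, logical(1)))

  structure(list(k = k_hat, partition = part, kmeans_partition = km,
                 kmeans_agreement = rand_index(part, km),
                 stable = stable, wss = wss, hclust = hc, features = X),
            class = "cohort_clustering")
}
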