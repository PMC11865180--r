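#' Paired t-test with Cohen's d and a JZS Bayes factor
#'
#' Two-sided paired (or one-sample) t-test via [stats::t.test()], augmented
#' with the paired-data Cohen's d (mean difference divided by the standard
#' deviation of the differences, so `d = |t| / sqrt(n)`) and the default
#' JZS Bayes factor of [jzs_bf_paired()].
#'
#' @param x,y Paired numeric vectors (`y = NULL` for a one-sample test on
#'   `x`).
#' @param r_scale Cauchy prior scale for the Bayes factor.
#' @param bf Compute the Bayes factor? (Skip for speed in simulations.)
#' @param comparison Label carried into the output.
#' @return A one-row tibble: `comparison`, `n`, `statistic`, `df`,
#'   `p_value`, `cohens_d`, `bf10`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 5), c(0, 1, 1, 2))
paired_t <- function(x, y = NULL, r_scale = sqrt(2) / 2, bf = TRUE,
                     comparison = "x - y") {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  stopifnot(n >= 2, is.null(y) || length(y) == length(x))
  if (stats::sd(d) == 0) {
    if (mean(d) != 0) {
      stop("zero variance of differences with non-zero mean", call. = FALSE)
    }
    tstat <- 0; pval <- 1
  } else {
    ht <- stats::t.test(d)
    tstat <- unname(ht$statistic); pval <- ht$p.value
  }
  tibble::tibble(
    comparison = comparison, n = n,
    statistic = tstat, df = n - 1, p_value = pval,
    cohens_d = if (stats::sd(d) == 0) 0 else mean(d) / stats::sd(d),
    bf10 = if (bf) jzs_bf_paired(tstat, n, r_scale) else NA_real_
  )
}

#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Default-prior Bayes factor for the t-test (Rouder et al., 2009): the
#' standardised effect size gets a Cauchy prior with scale `r_scale`
#' (equivalently, the Zellner-Siow inverse-gamma mixture over g), and BF10
#' is the ratio of the marginal likelihood under that prior to the point
#' null, evaluated by adaptive quadrature over g.
#'
#' @param t Observed t statistic.
#' @param n Number of (pairs of) observations.
#' @param r_scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return The Bayes factor BF10 (> 1 favours the alternative).
#' @export
#' @examples
#' jzs_bf_paired(4.87, 24)
jzs_bf_paired <- function(t, n, r_scale = sqrt(2) / 2) {
  stopifnot(n >= 2, r_scale > 0)
  nu <- n - 1
  integrand <- function(g) {
    (1 + n * g)^(-0.5) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      r_scale / sqrt(2 * pi) * g^(-1.5) * exp(-r_scale^2 / (2 * g))
  }
  num <- stats::integrate(integrand, 0, Inf,
                          rel.tol = 1e-10, subdivisions = 500L)
  if (num$message != "OK") {
    stop("Bayes factor quadrature did not converge", call. = FALSE)
  }
  num$value / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subjects one-way ANOVA (one observation per participant x
#' condition cell) fitted with [stats::aov()] and an `Error(participant)`
#' stratum, so the condition effect is tested against the participant x
#' condition interaction with df `(k - 1, (k - 1)(n - 1))`. No sphericity
#' correction is applied. Marginal means with their standard errors and
#' Tukey pairwise comparisons (studentized range on the within-subjects
#' error term) are included.
#'
#' @param data Long-format data frame.
#' @param value,participant,condition Bare column names of the response,
#'   participant id and condition.
#' @return An `ec_anova` object; see [tidy.ec_anova()].
#' @export
#' @examples
#' dat <- tidyr::expand_grid(pid = 1:6, cond = c("A", "B", "C"))
#' dat$y <- stats::rnorm(nrow(dat)) + as.integer(factor(dat$cond))
#' rm_anova_oneway(dat, y, pid, cond)
rm_anova_oneway <- function(data, value, participant, condition) {
  d <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    pid = factor(dplyr::pull(data, {{ participant }})),
    cond = factor(dplyr::pull(data, {{ condition }}))
  )
  check_complete(d, "cond")
  fit <- stats::aov(y ~ cond + Error(pid), data = d)
  eff <- extract_effect(fit, "cond", scale_ss = sum((d$y - mean(d$y))^2))
  eff$effect <- "condition"
  emm <- d |>
    dplyr::group_by(level = .data$cond) |>
    dplyr::summarise(
      mean = mean(.data$y),
      se = stats::sd(.data$y) / sqrt(dplyr::n()), .groups = "drop"
    )
  means <- stats::setNames(emm$mean, as.character(emm$level))
  tk <- tukey_ranges(
    means, eff$error_ms, eff$df2, nlevels(d$pid)
  )
  structure(
    list(
      design = "oneway", n = nlevels(d$pid),
      effects = eff[, c("effect", "df1", "df2", "statistic", "p_value")],
      emmeans = emm, tukey = tk$table, chain = tk$chain
    ),
    class = "ec_anova"
  )
}

#' Factorial (3 x 3) repeated-measures ANOVA
#'
#' Fully within-subjects two-factor ANOVA (one observation per participant
#' per cell), fitted with [stats::aov()] and `Error(pid/(A*B))` strata so
#' each effect is tested against its own participant-interaction error term:
#' main effects with df `(a - 1, (a - 1)(n - 1))` and the interaction with
#' `((a-1)(b-1), (a-1)(b-1)(n-1))`. Uncorrected F. Includes marginal means
#' and SEs per factor, Tukey post hocs on each main effect (using that
#' factor's error term, with `n x b` scores per marginal mean), and simple
#' effects of each factor within the levels of the other (Tukey on cell
#' means against the interaction error term).
#'
#' @param data Long-format data frame, one row per participant x cell.
#' @param value,participant,factor_a,factor_b Bare column names.
#' @return An `ec_anova` object.
#' @export
rm_anova_3x3 <- function(data, value, participant, factor_a, factor_b) {
  d <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    pid = factor(dplyr::pull(data, {{ participant }})),
    A = factor(dplyr::pull(data, {{ factor_a }})),
    B = factor(dplyr::pull(data, {{ factor_b }}))
  )
  check_complete(d, c("A", "B"))
  fit <- stats::aov(y ~ A * B + Error(pid / (A * B)), data = d)
  ss_y <- sum((d$y - mean(d$y))^2)
  effA <- extract_effect(fit, "A", scale_ss = ss_y)
  effB <- extract_effect(fit, "B", scale_ss = ss_y)
  effAB <- extract_effect(fit, "A:B", scale_ss = ss_y)
  effects <- dplyr::bind_rows(
    dplyr::mutate(effA, effect = "A"),
    dplyr::mutate(effB, effect = "B"),
    dplyr::mutate(effAB, effect = "A:B")
  )
  n <- nlevels(d$pid)
  marg <- function(fac) {
    d |>
      dplyr::group_by(level = .data[[fac]]) |>
      dplyr::summarise(
        mean = mean(.data$y),
        se = stats::sd(.data$y) / sqrt(dplyr::n()), .groups = "drop"
      ) |>
      dplyr::mutate(factor = fac, .before = 1)
  }
  emm <- dplyr::bind_rows(marg("A"), marg("B"))
  tk_main <- function(fac, eff, n_other) {
    e <- emm[emm$factor == fac, ]
    tukey_ranges(
      stats::setNames(e$mean, as.character(e$level)),
      eff$error_ms, eff$df2, n * n_other
    )
  }
  tkA <- tk_main("A", effA, nlevels(d$B))
  tkB <- tk_main("B", effB, nlevels(d$A))
  tukey <- dplyr::bind_rows(
    dplyr::mutate(tkA$table, factor = "A", .before = 1),
    dplyr::mutate(tkB$table, factor = "B", .before = 1)
  )
  simple <- purrr::map_dfr(levels(d$B), function(bl) {
    cm <- d |>
      dplyr::filter(.data$B == bl) |>
      dplyr::group_by(.data$A) |>
      dplyr::summarise(mean = mean(.data$y), .groups = "drop")
    tukey_ranges(
      stats::setNames(cm$mean, as.character(cm$A)),
      effAB$error_ms, effAB$df2, n
    )$table |>
      dplyr::mutate(within = paste0("B=", bl), .before = 1)
  })
  simple <- dplyr::bind_rows(
    simple,
    purrr::map_dfr(levels(d$A), function(al) {
      cm <- d |>
        dplyr::filter(.data$A == al) |>
        dplyr::group_by(.data$B) |>
        dplyr::summarise(mean = mean(.data$y), .groups = "drop")
      tukey_ranges(
        stats::setNames(cm$mean, as.character(cm$B)),
        effAB$error_ms, effAB$df2, n
      )$table |>
        dplyr::mutate(within = paste0("A=", al), .before = 1)
    })
  )
  structure(
    list(
      design = "factorial", n = n,
      effects = effects[, c("effect", "df1", "df2", "statistic", "p_value")],
      emmeans = emm, tukey = tukey,
      chain = c(A = tkA$chain, B = tkB$chain),
      simple_effects = simple
    ),
    class = "ec_anova"
  )
}

# All participants must have exactly one observation per cell.
check_complete <- function(d, facs) {
  counts <- dplyr::count(d, dplyr::across(dplyr::all_of(c("pid", facs))))
  k <- prod(vapply(facs, function(f) nlevels(d[[f]]), integer(1)))
  per_pid <- dplyr::count(counts, .data$pid)
  if (any(counts$n != 1) || any(per_pid$n != k)) {
    stop("design must be complete and balanced: one observation per ",
         "participant per cell", call. = FALSE)
  }
}

# Pull one effect's F test and error MS out of a summary.aovlist. An effect
# whose sum of squares is numerically zero relative to the response's total
# variation is reported as F = 0 (the 0/0 case when the error stratum is
# also empty would otherwise surface rounding noise).
extract_effect <- function(fit, term, scale_ss = 1) {
  for (stratum in summary(fit)) {
    tab <- if (inherits(stratum, "summary.aov")) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    if (term %in% rn) {
      i <- match(term, rn)
      j <- match("Residuals", rn)
      f <- tab$`F value`[i]
      p <- tab$`Pr(>F)`[i]
      if (is.na(f) || tab$`Sum Sq`[i] <= 1e-12 * (scale_ss + 1e-300)) {
        f <- 0
        p <- 1
      }
      return(tibble::tibble(
        effect = term,
        df1 = tab$Df[i], df2 = tab$Df[j],
        statistic = f, p_value = p,
        error_ms = tab$`Mean Sq`[j]
      ))
    }
  }
  stop("effect not found in model: ", term, call. = FALSE)
}

#' Tukey pairwise comparisons from summary statistics
#'
#' Studentized-range (Tukey HSD) adjusted p-values for all pairs of `k`
#' means sharing an error term: `q = |diff| / sqrt(error_ms / n_per_mean)`
#' referred to the studentized range distribution with `k` groups and
#' `error_df` degrees of freedom. Also reports the means ordered as a chain,
#' adjacent means joined by `>` when their pairwise comparison is
#' significant at `alpha` and `=` otherwise.
#'
#' @param means Named numeric vector of condition means.
#' @param error_ms,error_df Error mean square and its df.
#' @param n_per_mean Number of scores per mean.
#' @param alpha Significance level for the chain.
#' @return A list: `table` (pair, diff, q, p_adj) and `chain` (character).
#' @export
#' @examples
#' tukey_ranges(c(M = 0.22, O = 0.30, N1 = 0.58), 0.01, 46, 24)
tukey_ranges <- function(means, error_ms, error_df, n_per_mean,
                         alpha = 0.05) {
  stopifnot(length(means) >= 2, !is.null(names(means)))
  if (error_df <= 0) stop("error_df must be positive", call. = FALSE)
  se <- sqrt(error_ms / n_per_mean)
  k <- length(means)
  pairs <- utils::combn(names(means), 2)
  diffs <- unname(means[pairs[1, ]] - means[pairs[2, ]])
  qs <- abs(diffs) / se
  tab <- tibble::tibble(
    pair = paste(pairs[1, ], "-", pairs[2, ]),
    diff = diffs,
    q = qs,
    p_adj = stats::ptukey(qs, k, error_df, lower.tail = FALSE)
  )
  ord <- names(sort(means, decreasing = TRUE))
  sym <- vapply(seq_len(k - 1), function(i) {
    pj <- tab$p_adj[(pairs[1, ] == ord[i] & pairs[2, ] == ord[i + 1]) |
                      (pairs[1, ] == ord[i + 1] & pairs[2, ] == ord[i])]
    if (pj < alpha) " > " else " = "
  }, character(1))
  chain <- paste0(ord[1], paste0(sym, ord[-1], collapse = ""))
  list(table = tab, chain = chain)
}

#' @export
print.ec_anova <- function(x, ...) {
  cat(sprintf("<ec_anova: %s repeated-measures design, n = %d>\n",
              x$design, x$n))
  print(as.data.frame(x$effects), row.names = FALSE)
  cat("Tukey chain:", paste(x$chain, collapse = "; "), "\n")
  invisible(x)
}
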