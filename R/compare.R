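#' Probability that two VO2 measures are the same
#'
#' The front-end test-retest analysis. Each VO2 value is combined with its
#' device's sigma(mu) calibration to form a normal error distribution, and
#' the overlapping coefficient of the two densities is returned as the
#' probability that the two measures are the same. When no system is given,
#' the ParvoMedics 2400 TrueOne is assumed for that measure.
#'
#' @param a,b The two VO2 values (L/min); positive.
#' @param system_a,system_b Device labels for each measure (default
#'   `"parvo_2400"`; the other shipped device is `"douglas_bag"`).
#' @param threshold Similarity threshold for the verdict (default 0.10): a
#'   probability strictly below it is classified "truly different".
#' @param registry Calibration registry; defaults to the shipped one.
#' @return An object of class `comparison_result`: `prob_same`, `verdict`,
#'   `threshold`, and an `inputs` echo (values, systems, sigmas).
#' @examples
#' \dontrun{
#' vo2_compare(1.5, 1.7)                       # ParvoMedics both days
#' vo2_compare(3.0, 3.3, "douglas_bag", "parvo_2400")  # mixed systems
#' }
#' @export
vo2_compare <- function(a, b, system_a = "parvo_2400", system_b = "parvo_2400",
                        threshold = 0.10, registry = default_registry()) {
  da <- make_distribution(a, system_a, registry)
  db <- make_distribution(b, system_b, registry)
  prob <- ovl_normal(da$mu, da$sigma, db$mu, db$sigma)
  structure(
    list(
      prob_same = prob,
      verdict = classify_similarity(prob, threshold),
      threshold = threshold,
      inputs = list(
        mu_a = a, system_a = system_a, sigma_a = da$sigma,
        mu_b = b, system_b = system_b, sigma_b = db$sigma
      )
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "VO2 comparison: %g L/min (%s) vs %g L/min (%s)\n",
    x$inputs$mu_a, x$inputs$system_a, x$inputs$mu_b, x$inputs$system_b
  ))
  cat(sprintf("  probability same: %.3f (%.1f%%)\n",
              x$prob_same, 100 * x$prob_same))
  cat(sprintf("  verdict at %.0f%% threshold: %s\n",
              100 * x$threshold, x$verdict))
  invisible(x)
}

#' Classify a similarity probability against a threshold
#'
#' Measures are called "truly different" when the probability of similarity
#' falls strictly below the threshold; a probability equal to the threshold
#' is "not distinguishable" (equality is not below the bar). The 10% default
#' is a reasonable convention, not a law; choose a threshold that fits the
#' clinical or research context.
#'
#' @param prob_same Probability in \[0, 1\].
#' @param threshold Probability strictly in (0, 1); default 0.10.
#' @return `"truly different"` or `"not distinguishable"`.
#' @export
classify_similarity <- function(prob_same, threshold = 0.10) {
  check_scalar_number(prob_same, "prob_same")
  check_scalar_number(threshold, "threshold")
  if (prob_same < 0 || prob_same > 1) {
    abort_invalid_input("`prob_same` must lie in [0, 1]")
  }
  if (threshold <= 0 || threshold >= 1) {
    abort_invalid_input("`threshold` must lie strictly in (0, 1)")
  }
  if (prob_same < threshold) "truly different" else "not distinguishable"
}

#' Net probability of similarity across a cohort ("stacked" analysis)
#'
#' Applies [vo2_compare()] to each positionally matched pre/post pair and
#' returns the arithmetic mean of the per-pair similarity probabilities. One
#' pair of systems applies to the whole batch; for per-row systems use
#' [compare_batch()].
#'
#' @param pre,post Numeric vectors of VO2 values (L/min), equal length >= 1.
#' @inheritParams vo2_compare
#' @return The net probability of similarity (a single number).
#' @export
net_similarity <- function(pre, post, system_a = "parvo_2400",
                           system_b = "parvo_2400",
                           registry = default_registry()) {
  if (!is.numeric(pre) || !is.numeric(post)) {
    abort_invalid_input("`pre` and `post` must be numeric vectors")
  }
  if (length(pre) == 0L || length(post) == 0L) {
    abort_invalid_input("`pre` and `post` must be non-empty")
  }
  if (length(pre) != length(post)) {
    abort_invalid_input(sprintf(
      "`pre` and `post` must have equal length (got %d and %d)",
      length(pre), length(post)
    ))
  }
  probs <- mapply(function(a, b) {
    vo2_compare(a, b, system_a, system_b, registry = registry)$prob_same
  }, pre, post)
  mean(probs)
}

#' Batch comparison of a cohort data frame
#'
#' Runs [vo2_compare()] on every row of a batch table and appends the net
#' probability of similarity. Per-row device columns `system_pre` /
#' `system_post` override the batch-level defaults where present.
#'
#' @param data A data.frame with columns `pre_vo2`, `post_vo2`, optionally
#'   `subject_id`, `system_pre`, `system_post`.
#' @inheritParams vo2_compare
#' @return A data.frame with columns `subject_id`, `pre_vo2`, `post_vo2`,
#'   `system_pre`, `system_post`, `prob_same`, `verdict`; the net probability
#'   is attached as attribute `net_similarity`.
#' @export
compare_batch <- function(data, system_a = "parvo_2400",
                          system_b = "parvo_2400", threshold = 0.10,
                          registry = default_registry()) {
  if (!is.data.frame(data) || !all(c("pre_vo2", "post_vo2") %in% names(data))) {
    abort_invalid_input("`data` must be a data.frame with pre_vo2 and post_vo2 columns")
  }
  if (nrow(data) == 0L) abort_invalid_input("batch table has no rows")
  sys_pre <- if ("system_pre" %in% names(data)) data$system_pre else rep(system_a, nrow(data))
  sys_post <- if ("system_post" %in% names(data)) data$system_post else rep(system_b, nrow(data))
  sid <- if ("subject_id" %in% names(data)) data$subject_id else seq_len(nrow(data))

  rows <- lapply(seq_len(nrow(data)), function(i) {
    res <- vo2_compare(data$pre_vo2[i], data$post_vo2[i],
                       sys_pre[i], sys_post[i],
                       threshold = threshold, registry = registry)
    data.frame(
      subject_id = as.character(sid[i]),
      pre_vo2 = data$pre_vo2[i], post_vo2 = data$post_vo2[i],
      system_pre = sys_pre[i], system_post = sys_post[i],
      prob_same = res$prob_same, verdict = res$verdict,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "net_similarity") <- mean(out$prob_same)
  out
}

#' Plot two measurement distributions and their overlap
#'
#' Draws the two normal densities over
#' \eqn{[\min(\mu) - 4\max(\sigma),\ \max(\mu) + 4\max(\sigma)]} with the
#' shared (pointwise-minimum) region shaded dark, annotated with the overlap
#' coefficient to three decimals.
#'
#' @param result A `comparison_result` from [vo2_compare()].
#' @param file Optional output path; written with [ggplot2::ggsave()] (format
#'   by extension, e.g. `.png`, `.pdf`, `.svg`).
#' @param width,height Device size in inches when writing a file.
#' @return The ggplot object, invisibly when a file is written.
#' @export
plot_overlap <- function(result, file = NULL, width = 7, height = 5) {
  if (!inherits(result, "comparison_result")) {
    abort_invalid_input("`result` must be a comparison_result from vo2_compare()")
  }
  inp <- result$inputs
  smax <- max(inp$sigma_a, inp$sigma_b)
  x <- seq(min(inp$mu_a, inp$mu_b) - 4 * smax,
           max(inp$mu_a, inp$mu_b) + 4 * smax, length.out = 600L)
  f_a <- stats::dnorm(x, inp$mu_a, inp$sigma_a)
  f_b <- stats::dnorm(x, inp$mu_b, inp$sigma_b)
  dens <- data.frame(
    x = rep(x, 2L),
    density = c(f_a, f_b),
    measure = rep(c(
      sprintf("a: %g L/min (%s)", inp$mu_a, inp$system_a),
      sprintf("b: %g L/min (%s)", inp$mu_b, inp$system_b)
    ), each = length(x))
  )
  shade <- data.frame(x = x, density = pmin(f_a, f_b))

  p <- ggplot2::ggplot(dens, ggplot2::aes(x = x, y = density)) +
    ggplot2::geom_area(
      data = shade, fill = "grey25", alpha = 0.85,
      ggplot2::aes(x = x, y = density)
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = measure), linewidth = 0.9) +
    ggplot2::annotate(
      "text", x = mean(range(x)), y = max(dens$density) * 1.05,
      label = sprintf("overlap = %.3f", result$prob_same), size = 4.5
    ) +
    ggplot2::labs(
      x = expression(VO[2] ~ "(L/min)"), y = "density", colour = NULL,
      title = "Test-retest measurement-error distributions"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")

  if (!is.null(file)) {
    if (!dir.exists(dirname(file))) {
      abort_io(sprintf("cannot write plot: directory does not exist: %s", dirname(file)))
    }
    ggplot2::ggsave(file, plot = p, width = width, height = height)
    return(invisible(p))
  }
  p
}
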