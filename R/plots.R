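#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_abline
#'   geom_errorbar facet_wrap labs theme_minimal position_stack
NULL

#' Stacked haplotype frequency profile of a table
#'
#' @param table a [hap_table].
#' @return a ggplot.
#' @export
plot_haplotype_frequencies <- function(table) {
  m <- hap_counts(table)
  df <- tibble::tibble(
    pop = rep(colnames(m), each = nrow(m)),
    haplotype = rep(rownames(m), times = ncol(m)),
    freq = as.numeric(sweep(m, 2, colSums(m), "/"))
  )
  ggplot(df, aes(x = .data$pop, y = .data$freq, fill = .data$haplotype)) +
    geom_col(position = position_stack()) +
    labs(x = NULL, y = "haplotype frequency",
         title = sprintf("Haplotype profiles (%s)", hap_locus(table))) +
    theme_minimal()
}

#' @rdname fit_many_to_many
#' @param object an `msa_fit`.
#' @param view `"feeding"` (source contributions per feeding ground) or
#'   `"rookery"` (destination shares per rookery).
#' @param ... unused.
#' @export
autoplot.msa_fit <- function(object, view = c("feeding", "rookery"), ...) {
  view <- match.arg(view)
  df <- tidy.msa_fit(object, view = view)
  if (view == "feeding") {
    ggplot(df, aes(x = .data$feeding_ground, y = .data$mean, fill = .data$rookery)) +
      geom_col(position = position_stack()) +
      labs(x = "feeding ground", y = "posterior mean contribution",
           title = "Feeding-ground-centric origins") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$rookery, y = .data$mean, fill = .data$destination)) +
      geom_col(position = position_stack()) +
      labs(x = "rookery", y = "posterior mean destination share",
           title = "Rookery-centric destinations") +
      theme_minimal()
  }
}

#' @rdname origin_posterior
#' @param object an `origin_posterior`.
#' @param ... unused.
#' @export
autoplot.origin_posterior <- function(object, ...) {
  df <- tidy.origin_posterior(object)
  ggplot(df, aes(x = .data$target, y = .data$prob, fill = .data$rookery)) +
    geom_col(position = position_stack()) +
    labs(x = "target region", y = "P(rookery | target)",
         title = "Drifter-based natal origin probabilities") +
    theme_minimal()
}

#' @rdname log_profile_regression
#' @param object a `profile_regression`.
#' @param ... unused.
#' @export
autoplot.profile_regression <- function(object, ...) {
  ggplot(object$data, aes(x = .data$log_genetic, y = .data$log_drifter)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope) +
    labs(x = "log genetic origin proportion", y = "log drifter origin proportion",
         title = sprintf("Genetic vs drifter profiles (r = %.2f)", object$r)) +
    theme_minimal()
}

#' @rdname amova
#' @param object an `amova_fit`.
#' @param ... unused.
#' @export
autoplot.amova_fit <- function(object, ...) {
  df <- object$components
  df$level <- factor(df$level, levels = df$level)
  ggplot(df, aes(x = .data$level, y = .data$pct)) +
    geom_col() +
    labs(x = NULL, y = "% of molecular variance",
         title = sprintf("AMOVA variance partition (%s)", object$metric)) +
    theme_minimal()
}
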