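## ggplot2 views of the main result types.

#' @rdname merge_gene_sets
#' @param object a `merge_result`.
#' @export
autoplot.merge_result <- function(object, ...) {
  d <- object$decisions %>% count(status)
  ggplot2::ggplot(d, ggplot2::aes(x = status, y = n, fill = status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "old genes",
                  title = "Merge decisions for the old gene set") +
    ggplot2::theme_minimal()
}

#' @rdname classify_correspondence
#' @param object a `correspondence_report`.
#' @export
autoplot.correspondence_report <- function(object, ...) {
  d <- tidy(object) %>% count(class)
  ggplot2::ggplot(d, ggplot2::aes(x = class, y = n, fill = class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Gene correspondence between annotation versions") +
    ggplot2::theme_minimal()
}

#' @rdname conservation_analysis
#' @param object a `conservation_result` tibble.
#' @param ... unused.
#' @export
autoplot.conservation_result <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = n_conserved, y = -log10(p_value))
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "conserved miRNA-target pairs",
      y = expression(-log[10](p)),
      title = "Cross-species conservation of miRNA target repertoires"
    ) +
    ggplot2::theme_minimal()
}

#' Multiplicity distribution of intron candidates
#'
#' @param cands intron-candidate tibble.
#' @return a ggplot.
#' @export
plot_candidate_multiplicity <- function(cands) {
  ggplot2::ggplot(cands, ggplot2::aes(x = multiplicity)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "multiplicity (reads per intron candidate)",
                  y = "candidates") +
    ggplot2::theme_minimal()
}
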