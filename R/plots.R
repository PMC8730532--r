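#' Plot a brain map as tiled axial slices
#'
#' @param object a [brain_map()]
#' @param slices which third-axis slices to show (default: all)
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.brain_map <- function(object, slices = NULL, ...) {
  shape <- dim(object$volume)
  slices <- slices %||% seq_len(shape[3])
  df <- expand.grid(i = seq_len(shape[1]) - 1L, j = seq_len(shape[2]) - 1L,
                    k = slices - 1L)
  df$value <- object$volume[cbind(df$i + 1L, df$j + 1L, df$k + 1L)]
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~k, labeller = "label_both") +
    scale_fill_viridis_c(name = object$semantics) +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a heritability summary
#'
#' Bar chart of the proportion of regions above/below each threshold, per arm
#' and fraction.
#'
#' @param object a `herit_summary` from [summarize_heritability()]
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.herit_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("arm", "fraction",
                          grep("^pct_", names(object), value = TRUE))],
    cols = dplyr::starts_with("pct_"),
    names_to = "threshold", values_to = "pct")
  long$threshold <- sub("^pct_", "h2 ", gsub("_", " ", long$threshold))
  long$group <- sprintf("%s %s", long$arm,
                        ifelse(is.na(long$fraction), "",
                               sprintf("%g%%", 100 * long$fraction)))
  ggplot(long, aes(x = .data$threshold, y = .data$pct, fill = .data$group)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "% of regions") +
    theme_minimal()
}
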