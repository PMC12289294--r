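#' Plot the monthly adverse-event mention series
#'
#' Basic time-series figure with the key-event markers as dashed vertical
#' lines.
#'
#' @param monthly a [monthly_series()] result.
#' @return a ggplot object.
#' @export
plot_monthly_series <- function(monthly) {
  df <- as_tibble(monthly)
  df$month_date <- as.Date(paste0(df$month, "-01"))
  events <- attr(monthly, "key_events")
  p <- ggplot(df, aes(x = .data$month_date, y = .data$n_ae_mentions)) +
    geom_line(color = "steelblue") +
    geom_point(size = 0.8, color = "steelblue") +
    labs(x = NULL, y = "Adverse-event mentions per month") +
    theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p +
      geom_vline(xintercept = events$date, linetype = "dashed",
                 color = "grey40") +
      annotate("text", x = events$date, y = max(df$n_ae_mentions),
               label = stringr::str_wrap(events$label, 18),
               angle = 0, hjust = 0, vjust = 1, size = 2.4, color = "grey30")
  }
  p
}

#' Plot the co-occurrence network
#'
#' Node size proportional to mention frequency, node colour by community,
#' edge width by tier (thick for counts >= 100, moderate for 50-100, thin
#' below 50), positions from the seeded spring layout.
#'
#' @param graph a `cooccurrence_graph`.
#' @param layout a [spring_layout()] result.
#' @param partition optional [louvain()] result for node colours.
#' @return a ggplot object.
#' @export
plot_cooccurrence_network <- function(graph, layout, partition = NULL) {
  tiers <- tier_edges(graph)
  seg <- tiers |>
    left_join(layout, by = c(from = "ae_id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(layout, by = c(to = "ae_id"))
  nodes <- graph$nodes |> left_join(layout, by = "ae_id")
  nodes$community <- if (!is.null(partition)) {
    factor(partition$membership[nodes$ae_id])
  } else {
    factor(1)
  }
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x,
                     yend = .data$y, linewidth = .data$tier),
                 color = "grey70", alpha = 0.7) +
    scale_linewidth_manual(values = c(thin = 0.2, moderate = 0.9,
                                      thick = 2.0)) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$frequency,
                   color = .data$community)) +
    geom_text(data = nodes,
              aes(x = .data$x, y = .data$y, label = .data$ae_id),
              size = 2.3, vjust = -1.1) +
    scale_size_area(max_size = 9) +
    theme_void() +
    labs(color = "Community", size = "Posts", linewidth = "Co-occurrence")
}
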