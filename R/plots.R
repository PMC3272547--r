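#' Rose plot of circular data
#'
#' Base-graphics rose histogram of a set of angles (default 18 bins of
#' 20 degrees), with the mean resultant vector overlaid. Plotting never
#' affects computed statistics.
#'
#' @param angles numeric vector of angles in radians.
#' @param bins number of sectors.
#' @param main plot title.
#' @return Invisibly, the bin counts.
#' @export
plot_rose <- function(angles, bins = 18L, main = "") {
  counts <- rose_counts(angles, bins)
  k <- max(counts, 1L)
  breaks <- seq(-pi, pi, length.out = bins + 1L)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (b in seq_len(bins)) {
    r <- counts[b] / k
    if (r == 0) next
    th <- seq(breaks[b], breaks[b + 1L], length.out = 16L)
    graphics::polygon(c(0, r * cos(th)), c(0, r * sin(th)),
                      col = "grey70", border = "grey30")
  }
  s <- circ_summary(wrap_angle(angles))
  graphics::arrows(0, 0, s$rbar * cos(s$mean_direction),
                   s$rbar * sin(s$mean_direction),
                   col = "red", lwd = 2, length = 0.1)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey50")
  invisible(counts)
}

#' Plot tracks coloured by group
#'
#' @param tracks a [track_set()].
#' @param main plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_tracks <- function(tracks, main = "") {
  df <- as.data.frame(tracks)
  groups <- unique(df$group)
  cols <- stats::setNames(grDevices::hcl.colors(max(2L, length(groups)),
                                                "Dark 2"),
                          c(groups, rep("", max(0, 2 - length(groups)))))
  graphics::plot(df$x, df$y, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = main)
  for (id in unique(df$track_id)) {
    tr <- df[df$track_id == id, ]
    graphics::lines(tr$x, tr$y, col = cols[tr$group[1L]])
  }
  invisible(NULL)
}
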