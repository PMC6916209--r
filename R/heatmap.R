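#' Project patient features to 2-D with t-SNE
#'
#' Embeds the feature rows in the plane with the package's exact t-SNE
#' (stochastic neighbour embedding; quadratic cost, so intended for cohorts
#' of a few thousand samples). Deterministic under `seed`.
#'
#' @param features numeric matrix, one row per sample (e.g. Deep Features).
#' @param death_flags optional 0/1 flags carried alongside the points.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30; requires
#'   `n >= 3 * perplexity + 1`).
#' @param max_iter gradient-descent iterations.
#' @return list of class `embedding2d` with `points` (n x 2) and `died`.
#' @export
project_2d <- function(features, death_flags = NULL, seed = 1L,
                       perplexity = 30, max_iter = 300) {
  pts <- tsne_embed(features, perplexity = perplexity, max_iter = max_iter,
                    seed = seed)
  colnames(pts) <- c("x", "y")
  structure(list(points = pts,
                 died = if (!is.null(death_flags)) as.integer(death_flags)),
            class = "embedding2d")
}

#' Assign embedded points to a g x g grid
#'
#' Axis-aligned equal-width bins spanning the data's bounding box per axis;
#' the top edge is closed, so maximum-coordinate points land in the last
#' bin and every point gets a block.
#'
#' @param embedding an `embedding2d` (or a 2-column matrix).
#' @param g grid size per axis (30 in the reference configuration, giving 900 blocks).
#' @return data.frame with integer block coordinates `i`, `j` in `1..g`.
#' @export
grid_assign <- function(embedding, g = 30) {
  stopifnot(g >= 1)
  pts <- if (inherits(embedding, "embedding2d")) embedding$points else
    as.matrix(embedding)
  bin <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, length(v)))
    idx <- floor((v - rng[1]) / (rng[2] - rng[1]) * g) + 1L
    pmin(idx, g)
  }
  data.frame(i = bin(pts[, 1]), j = bin(pts[, 2]))
}

#' Smoothed block mortality rates
#'
#' For each block, `H = K / (N + F)` where `N` counts inpatient records in
#' the block, `K` counts those of patients who died, and `F` is a smoothing
#' factor (5 by default) that keeps a lone death record from reading as a
#' 100% mortality block; `F = 0` gives the raw rate.
#'
#' @param blocks data.frame from [grid_assign()].
#' @param death_flags 0/1 per point.
#' @param g grid size.
#' @param F smoothing factor, `>= 0`.
#' @return object of class `mortality_grid`: data.frame of all `g^2` blocks
#'   with `i`, `j`, `N`, `K`, `H`, plus attributes `g` and `F`.
#' @export
mortality_grid <- function(blocks, death_flags, g = 30, F = 5) {
  stopifnot(F >= 0, nrow(blocks) == length(death_flags))
  death_flags <- as.integer(death_flags)
  full <- expand.grid(i = seq_len(g), j = seq_len(g))
  key <- paste(blocks$i, blocks$j)
  fkey <- paste(full$i, full$j)
  full$N <- as.integer(table(factor(key, levels = fkey)))
  dk <- tapply(death_flags, factor(key, levels = fkey), sum)
  full$K <- as.integer(ifelse(is.na(dk), 0, dk))
  full$H <- full$K / (full$N + F)
  structure(full, class = c("mortality_grid", "data.frame"), g = g, F = F)
}

#' Plot a grid-mortality heatmap
#'
#' Darker blocks carry a higher smoothed mortality rate.
#'
#' @param grid a [mortality_grid()].
#' @return a ggplot object.
#' @export
plot_mortality_heatmap <- function(grid) {
  stopifnot(inherits(grid, "mortality_grid"))
  ggplot2::ggplot(as.data.frame(grid),
                  ggplot2::aes(x = .data$i, y = .data$j, fill = .data$H)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 name = "mortality") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Smoothed block mortality over the 2-D embedding") +
    ggplot2::theme_minimal()
}
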