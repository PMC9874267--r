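# Phase-plane objects: selection-gradient sign grids, nullclines, attractors
# and basins of attraction for the two coevolving resistance traits.

#' Evolutionary phase plane of the two resistance traits
#'
#' Evaluates the selection gradients on a lattice over the unit square of
#' (juvenile, adult) resistance, extracts the juvenile and adult nullclines
#' by sign-change contouring, finds and classifies the singular strategies,
#' and (optionally) labels each lattice cell with the basin of the attractor
#' it evolves to. Basins are computed by integrating the normalised
#' canonical-equation flow (trait velocities proportional to the selection
#' gradients, equal mutational input in both traits) through a bilinear
#' interpolation of the lattice gradient field. Cells where the host is not
#' viable or the disease cannot persist are labelled in `status`.
#'
#' @param params A one-row `host_params` tibble.
#' @param grid_n Lattice resolution per trait (default 21).
#' @param basins Compute basin labels (default `TRUE`).
#' @return An object of class `phase_plane`: list with `grid` (tibble `rJ`,
#'   `rA`, `dwJ`, `dwA`, `status`, `basin`), `nullclines` (tibble `stage`,
#'   `piece`, `rJ`, `rA`), `attractors` / `singular_points` (tibbles as
#'   returned by [find_cosingular()]) and `params`.
#' @examples
#' \donttest{
#' pp <- host_params(beta0 = 8, f = 0.1,
#'                   juvenile_target = "juvenile_mortality",
#'                   adult_target = "reproduction") |> phase_plane(grid_n = 11)
#' glance(pp)
#' }
#' @export
phase_plane <- function(params, grid_n = 21, basins = TRUE) {
  validate_params(params)
  p <- plist(params)
  params1 <- as_tibble(params)[1, ]
  grid <- gradient_grid(p, grid_n, allow_df = TRUE)
  grid$status <- grid$kind
  grid$kind <- NULL
  sing <- find_cosingular_core(params1, p, grid, grid_n = grid_n)
  attractors <- dplyr::filter(sing, .data$attractor %in% TRUE)
  nulls <- nullclines_from_grid(grid)
  grid$basin <- NA_integer_
  if (basins && nrow(attractors) > 0) {
    grid$basin <- basin_labels(grid, attractors)
  }
  structure(list(grid = grid, nullclines = nulls,
                 singular_points = sing, attractors = attractors,
                 params = params1),
            class = "phase_plane")
}

nullclines_from_grid <- function(grid) {
  rs <- sort(unique(grid$rJ))
  n <- length(rs)
  pieces <- list()
  for (stage in c("juvenile", "adult")) {
    z <- matrix(if (stage == "juvenile") grid$dwJ else grid$dwA, n, n)
    if (all(is.na(z))) next
    zz <- z
    zz[is.na(zz)] <- max(abs(z), na.rm = TRUE) + 1  # mask void regions
    cl <- grDevices::contourLines(rs, rs, zz, levels = 0)
    for (k in seq_along(cl)) {
      pieces <- c(pieces, list(tibble(stage = stage, piece = k,
                                      rJ = cl[[k]]$x, rA = cl[[k]]$y)))
    }
  }
  if (length(pieces) == 0) {
    tibble(stage = character(), piece = integer(), rJ = numeric(),
           rA = numeric())
  } else {
    dplyr::bind_rows(pieces)
  }
}

# bilinear interpolation of the gradient field; NA outside endemic region
interp_grad <- function(rs, mJ, mA, x) {
  n <- length(rs)
  i <- findInterval(x[1], rs, all.inside = TRUE)
  j <- findInterval(x[2], rs, all.inside = TRUE)
  tx <- (x[1] - rs[i]) / (rs[i + 1] - rs[i])
  ty <- (x[2] - rs[j]) / (rs[j + 1] - rs[j])
  bil <- function(m) {
    (1 - tx) * (1 - ty) * m[i, j] + tx * (1 - ty) * m[i + 1, j] +
      (1 - tx) * ty * m[i, j + 1] + tx * ty * m[i + 1, j + 1]
  }
  c(bil(mJ), bil(mA))
}

basin_labels <- function(grid, attractors) {
  rs <- sort(unique(grid$rJ))
  n <- length(rs)
  mJ <- matrix(grid$dwJ, n, n)
  mA <- matrix(grid$dwA, n, n)
  att <- cbind(attractors$rJ_star, attractors$rA_star)
  radius <- max(0.03, 0.75 / n)
  h <- 0.5 / n
  vapply(seq_len(nrow(grid)), function(k) {
    if (!grid$status[k] %in% c("endemic", "disease_free")) {
      return(NA_integer_)
    }
    x <- c(grid$rJ[k], grid$rA[k])
    for (step in seq_len(40 * n)) {
      d <- sqrt((att[, 1] - x[1])^2 + (att[, 2] - x[2])^2)
      if (any(d < radius)) return(which.min(d))
      g <- interp_grad(rs, mJ, mA, x)
      if (any(!is.finite(g))) return(NA_integer_)
      nrm <- sqrt(sum(g^2))
      if (nrm < 1e-12) return(which.min(d))
      x <- pmin(pmax(x + h * g / nrm, 0), 1)
    }
    d <- sqrt((att[, 1] - x[1])^2 + (att[, 2] - x[2])^2)
    if (min(d) < 3 * radius) which.min(d) else NA_integer_
  }, integer(1))
}

#' @export
print.phase_plane <- function(x, ...) {
  cat("<phase_plane>", nrow(x$grid), "lattice points,",
      nrow(x$attractors), "attractor(s),",
      length(unique(stats::na.omit(x$grid$basin))), "basin(s)\n")
  invisible(x)
}

#' @describeIn phase_plane `tidy()` returns the lattice (long format, one row
#'   per grid point) with gradients, gradient signs, status and basin label.
#' @param x A `phase_plane` object.
#' @param ... Unused.
#' @method tidy phase_plane
#' @export
tidy.phase_plane <- function(x, ...) {
  x$grid |>
    dplyr::mutate(dwJ_sign = sign(.data$dwJ), dwA_sign = sign(.data$dwA))
}

#' @describeIn phase_plane `glance()` returns one row with attractor/basin
#'   counts.
#' @method glance phase_plane
#' @export
glance.phase_plane <- function(x, ...) {
  tibble(n_grid = nrow(x$grid),
         n_singular = nrow(x$singular_points),
         n_attractors = nrow(x$attractors),
         n_basins = length(unique(stats::na.omit(x$grid$basin))))
}

#' @describeIn phase_plane `autoplot()` draws the basin raster, the juvenile
#'   (red) and adult (blue) nullclines and the attractors (purple points).
#' @param object A `phase_plane` object.
#' @method autoplot phase_plane
#' @export
autoplot.phase_plane <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$rJ, y = .data$rA))
  if (any(!is.na(object$grid$basin))) {
    g <- g + ggplot2::geom_raster(
      ggplot2::aes(fill = factor(.data$basin)), alpha = 0.35)
  }
  if (nrow(object$nullclines) > 0) {
    g <- g + ggplot2::geom_path(
      data = object$nullclines,
      ggplot2::aes(group = interaction(.data$stage, .data$piece),
                   colour = .data$stage))
  }
  if (nrow(object$attractors) > 0) {
    g <- g + ggplot2::geom_point(
      data = object$attractors,
      ggplot2::aes(x = .data$rJ_star, y = .data$rA_star),
      colour = "purple", size = 3)
  }
  g + ggplot2::scale_colour_manual(
    values = c(juvenile = "red", adult = "blue")) +
    ggplot2::labs(x = "juvenile resistance", y = "adult resistance",
                  fill = "basin", colour = "nullcline") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1))
}
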