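# Flow and sediment state containers.

#' Initialize the flow state
#'
#' Still water of uniform depth over a flat bed; obstacle cells are dry.
#'
#' @param grid `flood_grid`.
#' @param depth initial water depth (m).
#' @param bed initial bed elevation (m).
#' @param settings `numerical_settings` (for the background eddy viscosity).
#' @return list of class `flow_state`: matrices `h`, `u`, `v`, `z`, `nu`;
#'   the water surface is `H = h + z`.
#' @export
init_flow_state <- function(grid, depth = 1, bed = 10,
                            settings = numerical_settings()) {
  open <- grid$mask == 0L
  h <- matrix(0, grid$nx, grid$ny); h[open] <- depth
  z <- matrix(bed, grid$nx, grid$ny)
  nu <- matrix(settings$nu_background, grid$nx, grid$ny)
  structure(list(h = h, u = h * 0, v = h * 0, z = z, nu = nu),
            class = "flow_state")
}

#' Initialize the sediment state
#'
#' Uniform surface-layer composition equal to the mixture fractions, zero
#' suspended load.
#'
#' @param grid `flood_grid`.
#' @param mixture `grain_mixture`.
#' @return list of class `sediment_state`: `Ch` depth-integrated suspended
#'   concentration per class (nx x ny x nk), `p` surface-layer fractions
#'   (nx x ny x nk), plus the mixture.
#' @export
init_sediment_state <- function(grid, mixture) {
  nk <- length(mixture$class_diameters)
  Ch <- array(0, c(grid$nx, grid$ny, nk))
  p <- array(rep(mixture$fractions, each = grid$nx * grid$ny),
             c(grid$nx, grid$ny, nk))
  structure(list(Ch = Ch, p = p, mixture = mixture),
            class = "sediment_state")
}
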