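#' @export
print.pmf_curve <- function(x, ...) {
  cat(sprintf("pmf_curve (%s, x_ref = %g A):\n", attr(x, "method"),
              attr(x, "x_ref")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a potential of mean force
#'
#' @param x a \code{pmf_curve}.
#' @param add overlay on an existing plot.
#' @param col line/point colour.
#' @param ... further graphical parameters.
#' @export
plot.pmf_curve <- function(x, add = FALSE, col = if (attr(x, "method") == "PB") "firebrick" else "navy", ...) {
  if (!add) {
    plot(x$x, x$dG, type = "b", pch = 19, col = col,
         xlab = "separation x (Å)",
         ylab = expression(Delta * G ~ "(" * k[B] * T * ")"), ...)
    graphics::abline(h = 0, lty = 3, col = "grey50")
  } else {
    graphics::lines(x$x, x$dG, type = "b", pch = 19, col = col, ...)
  }
  if (any(x$dG_err > 0))
    graphics::arrows(x$x, x$dG - x$dG_err, x$x, x$dG + x$dG_err,
                     angle = 90, code = 3, length = 0.03, col = col)
  invisible(x)
}

#' Plot the two PMF routes of a comparison together
#'
#' @param x a \code{pmf_comparison}.
#' @param ... passed to \code{plot.pmf_curve}.
#' @export
plot.pmf_comparison <- function(x, ...) {
  ylim <- range(c(x$mc$curve$dG - x$mc$curve$dG_err,
                  x$mc$curve$dG + x$mc$curve$dG_err, x$pb$curve$dG, 0))
  plot(x$mc$curve, ylim = ylim,
       main = sprintf("|Z| = %ge, %g:%g salt, %g M", x$Z, x$z, x$z, x$c0),
       ...)
  plot(x$pb$curve, add = TRUE)
  graphics::legend("bottomright", legend = c("MC", "PB"), bty = "n",
                   col = c("navy", "firebrick"), lty = 1, pch = 19)
  invisible(x)
}

#' Plot a net ion charge profile
#'
#' @param x an \code{ion_charge_profile}.
#' @param add overlay on an existing plot.
#' @param col colour.
#' @param ... further graphical parameters.
#' @export
plot.ion_charge_profile <- function(x, add = FALSE,
                                    col = if (attr(x, "method") == "PB") "firebrick" else "navy",
                                    ...) {
  if (!add) {
    plot(x$r, x$Q, type = "l", col = col, xlab = "r (Å)",
         ylab = "Q(r)", ylim = c(0, max(x$Q, 1)), ...)
  } else graphics::lines(x$r, x$Q, col = col, ...)
  invisible(x)
}

#' Plot a charge-density landscape
#'
#' @param x a \code{charge_landscape}.
#' @param ... passed to \code{image}.
#' @export
plot.charge_landscape <- function(x, ...) {
  us <- sort(unique(x$u)); rs <- sort(unique(x$rho))
  m <- matrix(x$density, length(us), length(rs))
  lim <- max(abs(m), 1e-12)
  graphics::image(us, rs, m, zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(65, "Blue-Red 3"),
                  xlab = "axial u (Å)", ylab = "radial ρ (Å)",
                  ...)
  invisible(x)
}
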