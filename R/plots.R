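#' Box plots of kappa (or OOB error) across the depth ladder
#'
#' One box per depth level (full model first) built from the grid's
#' per-model values, with the kappa agreement bands shaded: above 0.8
#' almost perfect (green), below 0.6 poor (red).
#'
#' @param sweep result of [depthSweep()].
#' @param what `"kappa"` or `"oob_error"`.
#' @param main plot title.
#' @return invisibly, the list of per-level value vectors.
#' @export
plotDepthSweep <- function(sweep, what = c("kappa", "oob_error"),
                           main = NULL) {
  what <- match.arg(what)
  res <- c(list(sweep$full), sweep$levels)
  labs <- c("full", vapply(sweep$levels, function(r) format(r@depth),
                           character(1)))
  vals <- lapply(res, function(r) gridRecords(r)[[what]])
  names(vals) <- labs
  ylim <- if (what == "kappa") c(min(0, min(unlist(vals))), 1) else NULL
  graphics::boxplot(vals, las = 2, ylab = what, xlab = "depth level",
                    main = main, ylim = ylim, outline = TRUE)
  if (what == "kappa") {
    usr <- graphics::par("usr")
    graphics::rect(usr[1], 0.8, usr[2], usr[4],
                   col = grDevices::adjustcolor("darkgreen", 0.08),
                   border = NA)
    graphics::rect(usr[1], usr[3], usr[2], 0.6,
                   col = grDevices::adjustcolor("firebrick", 0.08),
                   border = NA)
    graphics::abline(h = c(0.6, 0.8), lty = 2, col = "grey40")
  }
  invisible(vals)
}

#' NMDS ordination scatter with class confidence ellipses
#'
#' @param report a [SeparabilityReport].
#' @param main plot title.
#' @return invisibly, the ordination data.frame.
#' @export
plotOrdination <- function(report, main = "NMDS (Bray-Curtis)") {
  stopifnot(is(report, "SeparabilityReport"))
  ords <- report@ordination
  cls <- factor(ords$class)
  cols <- grDevices::hcl.colors(nlevels(cls), "Dark 3")
  graphics::plot(ords$NMDS1, ords$NMDS2, col = cols[cls], pch = 19,
                 xlab = "NMDS1", ylab = "NMDS2", main = main, asp = 1)
  th <- seq(0, 2 * pi, length.out = 180)
  for (k in seq_len(nlevels(cls))) {
    xy <- as.matrix(ords[cls == levels(cls)[k], c("NMDS1", "NMDS2")])
    e <- .classEllipse(xy, report@confidence)
    ring <- cbind(cos(th), sin(th)) * sqrt(e$r2)
    ring <- sweep(ring %*% chol(e$S), 2L, e$mu, "+")
    graphics::lines(ring, col = cols[k], lwd = 2)
  }
  graphics::legend("topright", legend = levels(cls), col = cols,
                   pch = 19, bty = "n")
  invisible(ords)
}
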