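# Base-graphics views of the main results.

#' Plot a dinucleotide phasogram
#'
#' A/T-class frequency in blue, C/G-class frequency in red, against the
#' offset from the dyad.
#'
#' @param phasogram result of [computePhasogram()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotPhasogram <- function(phasogram, ...) {
    graphics::plot(phasogram$offsets, phasogram$ww_freq, type = "l",
                   col = "blue", xlab = "offset from dyad (bp)",
                   ylab = "dinucleotide frequency",
                   ylim = range(c(phasogram$ww_freq, phasogram$ss_freq)), ...)
    graphics::lines(phasogram$offsets, phasogram$ss_freq, col = "red")
    graphics::legend("topright", legend = c("AA/AT/TA/TT", "CC/CG/GC/GG"),
                     col = c("blue", "red"), lty = 1, bty = "n")
    invisible(NULL)
}

#' Plot one or more TSS-centred midpoint profiles
#'
#' @param profiles a \code{"TssProfile"} or named list of them (e.g. the
#'   strata of [stratifiedTssProfiles()]).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotTssProfile <- function(profiles, ...) {
    if (inherits(profiles, "TssProfile")) profiles <- list(profiles)
    cols <- grDevices::hcl.colors(max(3L, length(profiles)), "Dark 3")
    ylim <- range(unlist(lapply(profiles, `[[`, "rate")))
    graphics::plot(profiles[[1]]$offsets, profiles[[1]]$rate, type = "l",
                   col = cols[1], xlab = "offset from TSS (bp)",
                   ylab = "midpoints per TSS per bp", ylim = ylim, ...)
    if (length(profiles) > 1)
        for (i in 2:length(profiles))
            graphics::lines(profiles[[i]]$offsets, profiles[[i]]$rate,
                            col = cols[i])
    if (!is.null(names(profiles)))
        graphics::legend("topright", legend = names(profiles),
                         col = cols[seq_along(profiles)], lty = 1, bty = "n")
    invisible(NULL)
}

#' Scatter plot of a window comparison
#'
#' log10 FPKM of dataset a against dataset b with called windows
#' highlighted.
#'
#' @param comparison result of [compareWindows()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotWindowComparison <- function(comparison, ...) {
    w <- comparison$windows
    fa <- log10((w$count_a + 0.5) / (w$width / 1000) /
                    (comparison$total_a / 1e6))
    fb <- log10((w$count_b + 0.5) / (w$width / 1000) /
                    (comparison$total_b / 1e6))
    col <- ifelse(w$call == "enriched_in_a", "red",
                  ifelse(w$call == "enriched_in_b", "blue", "grey50"))
    graphics::plot(fb, fa, pch = 16, cex = 0.4, col = col,
                   xlab = "log10 FPKM (reference)",
                   ylab = "log10 FPKM (dataset)", ...)
    graphics::abline(0, 1, lty = 2)
    invisible(NULL)
}
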