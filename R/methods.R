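#' @export
print.ssgblup_rel <- function(x, ...) {
  cat("Single-step reliability approximation (APY)\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("  %d animals (%d genotyped), %d trait(s)\n",
              x$n_animals, length(x$genotyped_ids), length(x$traits)))
  fin <- x$table$rel_final
  cat(sprintf("  final reliability: mean %.3f, range [%.3f, %.3f]\n",
              mean(fin), min(fin), max(fin)))
  invisible(x)
}

#' Summary of a reliability approximation fit
#'
#' Per-trait, per-group (core / noncore / non-genotyped) means of the staged
#' reliabilities.
#'
#' @param object an `ssgblup_rel` fit.
#' @param ... unused.
#' @export
summary.ssgblup_rel <- function(object, ...) {
  tab <- object$table
  agg <- do.call(rbind, lapply(split(tab, list(tab$trait, tab$group),
                                     drop = TRUE), function(d) {
    data.frame(trait = d$trait[1L], group = d$group[1L], n = nrow(d),
               rel_pedigree = mean(d$rel_pedigree),
               rel_gblup = mean(d$rel_gblup),
               rel_a22 = mean(d$rel_a22),
               rel_final = mean(d$rel_final),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  out <- list(by_group = agg, traits = object$traits,
              timings = object$timings,
              n_animals = object$n_animals,
              n_genotyped = length(object$genotyped_ids))
  class(out) <- "summary.ssgblup_rel"
  out
}

#' @export
print.summary.ssgblup_rel <- function(x, ...) {
  cat("Single-step reliability approximation:",
      x$n_animals, "animals,", x$n_genotyped, "genotyped\n\n")
  print(x$by_group, digits = 3, row.names = FALSE)
  if (length(x$timings)) {
    cat("\nStage timings (s):\n")
    print(round(x$timings, 3))
  }
  invisible(x)
}

#' @export
as.data.frame.ssgblup_rel <- function(x, ...) x$table

#' Plot staged reliabilities
#'
#' Scatter of final against pedigree-stage reliabilities, one panel per
#' trait, colored by group; the diagonal marks where genomic information
#' adds nothing.
#'
#' @param x an `ssgblup_rel` fit.
#' @param ... passed to [plot()].
#' @export
plot.ssgblup_rel <- function(x, ...) {
  tab <- x$table
  nt <- length(x$traits)
  op <- graphics::par(mfrow = c(1, nt))
  on.exit(graphics::par(op))
  cols <- c(core = "firebrick", noncore = "steelblue",
            nongenotyped = "grey50")
  for (t in x$traits) {
    d <- tab[tab$trait == t, ]
    plot(d$rel_pedigree, d$rel_final, col = cols[d$group], pch = 20,
         cex = 0.6, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "pedigree reliability", ylab = "final reliability",
         main = t, ...)
    graphics::abline(0, 1, lty = 2)
  }
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   pch = 20, bty = "n")
  invisible(x)
}
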