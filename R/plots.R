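#' Plot category response curves
#'
#' @param fit A `rasch_fit`.
#' @param group Rating-scale group to plot.
#' @param ... Passed to [graphics::matplot()].
#' @return The [category_curves()] data, invisibly.
#' @export
plot_category_curves <- function(fit, group = names(fit$tau)[1], ...) {
  cc <- category_curves(fit, group)
  graphics::matplot(cc$grid, t(cc$probs), type = "l", lty = 1,
                    xlab = expression(theta - delta),
                    ylab = "Category probability",
                    main = sprintf("Category response curves (%s items)", group),
                    ...)
  graphics::abline(v = cc$tau, col = "grey80", lty = 3)
  invisible(cc)
}

#' Plot the test information curve
#'
#' @param fit A `rasch_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return The [test_information()] data, invisibly.
#' @export
plot_test_information <- function(fit, ...) {
  ti <- test_information(fit)
  graphics::plot(ti$theta, ti$information, type = "l",
                 xlab = "Interference with QoL (logits)",
                 ylab = "Information", main = "Test information curve", ...)
  invisible(ti)
}

#' Plot a person-to-item (Wright) map
#'
#' Person measures as a histogram on the left, item difficulties as
#' labelled points on the right, sharing one logit axis.
#'
#' @param fit A `rasch_fit`.
#' @return The [person_item_map()] data, invisibly.
#' @export
plot_person_item_map <- function(fit) {
  pim <- person_item_map(fit)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  h <- graphics::hist(pim$persons$theta, plot = FALSE)
  graphics::barplot(h$counts, horiz = TRUE, names.arg = NULL,
                    xlab = "Persons", main = "Person-to-item map")
  rng <- range(c(pim$persons$theta, pim$items$delta))
  graphics::plot(rep(0, nrow(pim$items)), pim$items$delta, pch = 16,
                 xlim = c(-0.2, 1), ylim = rng, xaxt = "n", xlab = "Items",
                 ylab = "Logits", main = "")
  graphics::text(0.05, pim$items$delta, pim$items$id, adj = 0, cex = 0.7)
  invisible(pim)
}
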