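# S3 methods for fitted FLAB segmentations.

#' @export
print.flab <- function(x, ...) {
  cat(sprintf("FLAB segmentation fit: %d classes, %d labels, %d ROI voxels\n",
              x$k, nrow(x$labels), length(x$data)))
  cat("Class means (SUV):", paste(format(x$means, digits = 4),
                                  collapse = ", "), "\n")
  cat("Class SDs  (SUV):", paste(format(x$sds, digits = 4),
                                 collapse = ", "), "\n")
  cv <- x$convergence
  cat(sprintf("%s after %d iterations (relative change %.2g)\n",
              if (cv$converged) "Converged" else "NOT converged",
              cv$iterations, cv$delta))
  invisible(x)
}

#' @export
summary.flab <- function(object, ...) {
  tab <- object$labels
  counts <- tabulate(object$label_map, nbins = nrow(tab))
  tab$n_voxels <- counts
  tab$fraction <- counts / sum(counts)
  out <- list(k = object$k, means = object$means, sds = object$sds,
              labels = tab, convergence = object$convergence,
              n = length(object$data), roi = object$roi)
  class(out) <- "summary.flab"
  out
}

#' @export
print.summary.flab <- function(x, ...) {
  cat(sprintf("FLAB fit over %d voxels, %d hard classes\n", x$n, x$k))
  cat("\nClass parameters:\n")
  print(data.frame(class = seq_len(x$k), mean = x$means, sd = x$sds),
        row.names = FALSE, digits = 4)
  cat("\nLabel occupancy:\n")
  df <- x$labels[, c("id", "type", "k_lo", "k_hi", "eps", "mu",
                     "n_voxels", "fraction")]
  print(df, row.names = FALSE, digits = 3)
  cat(sprintf("\n%s after %d iterations\n",
              if (x$convergence$converged) "Converged" else "Not converged",
              x$convergence$iterations))
  invisible(x)
}

#' @export
coef.flab <- function(object, ...) {
  setNames(c(object$means, object$sds),
           c(paste0("mean", seq_len(object$k)),
             paste0("sd", seq_len(object$k))))
}

#' Classify new intensities under a fitted FLAB model
#'
#' Uses the fitted label densities with the global (spatially averaged)
#' label frequencies as prior; no neighbourhood information is available
#' for out-of-image values.
#'
#' @param object a [flab()] fit.
#' @param newdata numeric intensities; default: the ROI data.
#' @param type `"class"` (hard class index, fuzzy labels mapped to their
#'   dominant class), `"label"` (label id) or `"posterior"` (matrix).
#' @param ... unused.
#' @export
predict.flab <- function(object, newdata = NULL,
                         type = c("class", "label", "posterior"), ...) {
  type <- match.arg(type)
  y <- newdata %||% object$data
  tab <- object$labels
  glob <- colMeans(object$posterior)
  dens <- vapply(seq_len(nrow(tab)), function(l)
    pmax(dnorm(y, tab$mu[l], tab$sd[l]), .Machine$double.xmin),
    numeric(length(y)))
  post <- dens * rep(glob, each = length(y))
  post <- post / rowSums(post)
  if (type == "posterior") {
    colnames(post) <- label_names(tab)
    return(post)
  }
  lab <- tab$id[max.col(post, ties.method = "first")]
  if (type == "label") return(lab)
  dom <- ifelse(tab$type == "hard", tab$k_lo,
                ifelse(tab$eps >= 0.5, tab$k_hi, tab$k_lo))
  dom[lab]
}

label_names <- function(tab) {
  ifelse(tab$type == "hard", paste0("class", tab$k_lo),
         sprintf("fuzzy%d-%d@%.2f", tab$k_lo, tab$k_hi, tab$eps))
}

#' @export
fitted.flab <- function(object, ...) {
  mu <- object$labels$mu[as.integer(object$label_map)]
  array(mu, dim(object$label_map))
}

#' @export
residuals.flab <- function(object, ...) {
  array(object$data, dim(object$label_map)) - fitted(object)
}

#' Draw synthetic intensities from a fitted FLAB mixture
#'
#' Labels are drawn from the global label frequencies and intensities
#' from the corresponding label densities.
#'
#' @param object a [flab()] fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param n draws per replicate (default: ROI size).
#' @param ... unused.
#' @return data.frame of `nsim` columns.
#' @export
simulate.flab <- function(object, nsim = 1, seed = NULL,
                          n = length(object$data), ...) {
  if (!is.null(seed)) set.seed(seed)
  glob <- colMeans(object$posterior)
  tab <- object$labels
  out <- replicate(nsim, {
    lab <- sample.int(nrow(tab), n, replace = TRUE, prob = glob)
    rnorm(n, tab$mu[lab], tab$sd[lab])
  })
  as.data.frame(out)
}

#' Plot a fitted FLAB segmentation
#'
#' Histogram of the ROI intensities overlaid with the fitted label
#' densities, weighted by their global frequencies; hard classes solid,
#' fuzzy levels dashed.
#'
#' @param x a [flab()] fit.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.flab <- function(x, breaks = 60, ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE,
                      main = "FLAB mixture fit",
                      xlab = "intensity (SUV)", border = "grey70", ...)
  glob <- colMeans(x$posterior)
  tab <- x$labels
  xs <- seq(min(x$data), max(x$data), length.out = 400)
  for (l in seq_len(nrow(tab))) {
    graphics::lines(xs, glob[l] * dnorm(xs, tab$mu[l], tab$sd[l]),
                    col = if (tab$type[l] == "hard") tab$k_lo[l] + 1 else
                      "grey40",
                    lty = if (tab$type[l] == "hard") 1 else 2)
  }
  tot <- rowSums(vapply(seq_len(nrow(tab)), function(l)
    glob[l] * dnorm(xs, tab$mu[l], tab$sd[l]), numeric(length(xs))))
  graphics::lines(xs, tot, lwd = 2)
  invisible(h)
}
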