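# S3 methods for cit_model.

count_params <- function(model) sum(vapply(model$params, length, numeric(1)))

#' @export
print.cit_model <- function(x, ...) {
  cat(sprintf("<cit_model> %s, %s parameters\n",
              if (x$trained) "trained" else "untrained",
              format(count_params(x), big.mark = ",")))
  print(x$config)
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs: final loss %.4f, train accuracy %.3f\n",
                nrow(x$history), last$loss, last$train_acc))
  }
  invisible(x)
}

#' @export
summary.cit_model <- function(object, ...) {
  grp <- sub("\\.(W|b|Wq|Wk|Wv|Wo|W1|W2|b1|b2|gamma|beta|pos)$", "",
             names(object$params))
  comp <- sub("^(stem|cnn|pe|tr|cit|head).*", "\\1", grp)
  sizes <- vapply(object$params, length, numeric(1))
  by_comp <- tapply(sizes, comp, sum)
  structure(list(config = object$config,
                 n_params = count_params(object),
                 params_by_component = by_comp,
                 history = object$history,
                 trained = object$trained),
            class = "summary.cit_model")
}

#' @export
print.summary.cit_model <- function(x, ...) {
  cat("CIT network summary\n===================\n")
  print(x$config)
  cat(sprintf("Parameters: %s total\n", format(x$n_params, big.mark = ",")))
  for (nm in names(x$params_by_component))
    cat(sprintf("  %-5s %12s\n", nm,
                format(x$params_by_component[[nm]], big.mark = ",")))
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf("Training: %d epochs, final loss %.4f, final train acc %.3f\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$history$train_acc[nrow(x$history)]))
  } else cat("Training: none\n")
  invisible(x)
}

#' @export
coef.cit_model <- function(object, ...) object$params

#' Plot training history
#'
#' Loss and training accuracy per epoch (base graphics).
#'
#' @param x A trained `cit_model`.
#' @param ... Passed to `plot`.
#' @export
plot.cit_model <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history))
    stop("plot.cit_model: no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", main = "Training loss", ...)
  plot(x$history$epoch, x$history$train_acc, type = "l", xlab = "epoch",
       ylab = "accuracy", ylim = c(0, 1), main = "Training accuracy", ...)
  invisible(x)
}
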