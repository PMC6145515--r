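#' Per-iteration solver trace
#'
#' A light record of a solver run: discrete energy per iterate (when
#' recorded), relative L2 update norm, optional PSNR versus a reference,
#' the iteration count, and how many intensity values were clamped at the
#' positivity floor.
#'
#' @param method solver label (`"m1"`, `"m2"`, `"m3"`, `"m4"`).
#' @param energies numeric vector (possibly empty), energy after each step.
#' @param rel_changes numeric vector, relative update norm per step.
#' @param psnr numeric vector (possibly empty), PSNR per step.
#' @param iterations completed iteration count.
#' @param clamp_count positivity-clamp events.
#' @param energy0 energy of the initial iterate (NA when not recorded).
#' @param diverged `TRUE` if the run stopped on a non-finite update.
#' @return a `solver_trace` object.
#' @export
solver_trace <- function(method, energies = numeric(), rel_changes = numeric(),
                         psnr = numeric(), iterations = length(rel_changes),
                         clamp_count = 0L, energy0 = NA_real_,
                         diverged = FALSE) {
  structure(list(method = method, energies = as.numeric(energies),
                 rel_changes = as.numeric(rel_changes),
                 psnr = as.numeric(psnr), iterations = as.integer(iterations),
                 clamp_count = as.integer(clamp_count),
                 energy0 = energy0, diverged = isTRUE(diverged)),
            class = "solver_trace")
}

#' @export
print.solver_trace <- function(x, ...) {
  cat(sprintf("<solver_trace %s: %d iterations%s, %d clamps%s>\n",
              x$method, x$iterations,
              if (length(x$psnr)) sprintf(", final PSNR %.2f dB",
                                          x$psnr[length(x$psnr)]) else "",
              x$clamp_count,
              if (x$diverged) ", DIVERGED" else ""))
  invisible(x)
}

#' Tidy a solver trace into one row per iteration
#'
#' @param x a `solver_trace`.
#' @param ... ignored.
#' @return a tibble with columns `iteration`, `rel_change`, and, when
#'   recorded, `energy` and `psnr_db`.
#' @exportS3Method generics::tidy
#' @export
tidy.solver_trace <- function(x, ...) {
  n <- x$iterations
  out <- tibble::tibble(iteration = seq_len(n),
                        rel_change = x$rel_changes[seq_len(n)])
  if (length(x$energies) >= n) out$energy <- x$energies[seq_len(n)]
  if (length(x$psnr) >= n) out$psnr_db <- x$psnr[seq_len(n)]
  out
}

#' One-row summary of a solver trace
#'
#' @inheritParams tidy.solver_trace
#' @return a one-row tibble.
#' @exportS3Method generics::glance
#' @export
glance.solver_trace <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    iterations = x$iterations,
    final_rel_change = if (x$iterations) x$rel_changes[x$iterations] else NA_real_,
    final_energy = if (length(x$energies)) x$energies[length(x$energies)] else NA_real_,
    final_psnr_db = if (length(x$psnr)) x$psnr[length(x$psnr)] else NA_real_,
    clamp_count = x$clamp_count,
    diverged = x$diverged
  )
}

#' Plot a solver trace
#'
#' Energy, relative change, and PSNR (whichever were recorded) against the
#' iteration index, on free vertical scales.
#'
#' @param object a `solver_trace`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.solver_trace <- function(object, ...) {
  td <- tidy(object)
  long <- do.call(rbind, lapply(setdiff(names(td), "iteration"), function(nm) {
    data.frame(iteration = td$iteration, quantity = nm, value = td[[nm]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = sprintf("solver trace (%s)", object$method)) +
    ggplot2::theme_minimal()
}
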