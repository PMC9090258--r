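# internal helpers shared across modules

#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  stop_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
          "`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Truncated normal draw on [a, b] by inverse-CDF; degenerates to `mean`
# when sd == 0 (mean must then lie in [a, b]).
#' @noRd
rtruncnorm <- function(n, mean, sd, a = -Inf, b = Inf) {
  if (n == 0L) return(numeric(0))
  if (all(sd == 0)) return(rep_len(pmin(pmax(mean, a), b), n))
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Columns every cell table must carry before spatial analysis.
#' @noRd
check_cell_table <- function(cells, cols = c("cell_id", "x_um", "y_um")) {
  stop_if(!is.data.frame(cells), "cell table must be a data.frame")
  missing <- setdiff(cols, names(cells))
  stop_if(length(missing) > 0,
          "cell table lacks column(s): ", paste(missing, collapse = ", "))
  invisible(cells)
}
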