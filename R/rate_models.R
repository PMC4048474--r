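#' Linear telomere-loss model
#'
#' Per-replication telomere loss `y(n) = y0 + y1 * n`, where `n` is the
#' current length (bp) of the telomere being eroded.  `y1 = 0` gives the
#' constant-loss model (case A1/B1); `y1 > 0` makes long telomeres lose more
#' basepairs per division than short ones (case A2/B2).
#'
#' @param y0 Baseline loss per replication, in basepairs (>= 0).
#' @param y1 Dimensionless slope (loss per bp of telomere, >= 0).
#' @return An object of class `telo_loss`.
#' @seealso [loss_y()], [preset_case()]
#' @export
#' @examples
#' loss_y(3000, loss_model(100, 1 / 30)) # 200
loss_model <- function(y0, y1 = 0) {
  stopifnot(is.numeric(y0), length(y0) == 1L, is.finite(y0), y0 >= 0,
            is.numeric(y1), length(y1) == 1L, is.finite(y1), y1 >= 0)
  structure(list(y0 = y0, y1 = y1), class = "telo_loss")
}

#' Evaluate the telomere-loss model
#'
#' @param n Telomere length(s) in basepairs (>= 0); vectorized.
#' @param loss A [loss_model()].
#' @return Basepairs lost per replication at each `n`.
#' @export
loss_y <- function(n, loss) {
  stopifnot(inherits(loss, "telo_loss"), is.numeric(n))
  if (any(n < 0)) stop("telomere length `n` must be non-negative")
  loss$y0 + loss$y1 * n
}

#' Length-dependent division-probability model
#'
#' Probability that a non-senescent individual divides in one generation:
#' `P_div(n) = (a + b * n)^alpha`, with the base clamped at 0 before
#' exponentiation and the result clamped to `[0, 1]`.  `alpha = 0` gives
#' `P_div = 1` (case A: divide whenever possible); `alpha = 1` gives a
#' linear probability (case B1/B2).
#'
#' @param a Dimensionless offset.
#' @param b Slope per basepair.
#' @param alpha Exponent in `[0, 1]`.
#' @return An object of class `telo_division`.
#' @export
#' @examples
#' dm <- division_model(-200 / 5750, 1 / 5750, 1)
#' p_div(5950, dm) # 1
#' p_div(200, dm)  # 0
division_model <- function(a, b, alpha) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(alpha), length(alpha) == 1L,
            alpha >= 0, alpha <= 1)
  structure(list(a = a, b = b, alpha = alpha), class = "telo_division")
}

#' Evaluate the division-probability model
#'
#' @param n Telomere length(s) in basepairs; vectorized.  For a cell this is
#'   the mean telomere length over all chromosome ends.
#' @param division A [division_model()].
#' @return Division probabilities in `[0, 1]`.
#' @export
p_div <- function(n, division) {
  stopifnot(inherits(division, "telo_division"), is.numeric(n))
  base <- pmax(division$a + division$b * n, 0)
  pmin(pmax(base ^ division$alpha, 0), 1)
}

#' Werner's-syndrome deletion parameters
#'
#' With probability `p_w` per chromosome replication, an extra block of `x`
#' basepairs is deleted at one of four strand/end positions (chosen
#' uniformly).  `p_w = x = 0` recovers normal aging.
#'
#' @param p_w Per-replication probability of an extra deletion, in `[0, 1]`.
#' @param x Size of the extra deletion in basepairs (>= 0).
#' @return An object of class `telo_werner`.
#' @seealso [preset_werner()]
#' @export
werner_params <- function(p_w, x) {
  stopifnot(is.numeric(p_w), length(p_w) == 1L, is.numeric(x),
            length(x) == 1L, is.finite(x), x >= 0)
  if (!is.finite(p_w) || p_w < 0 || p_w > 1)
    stop("`p_w` must be a probability in [0, 1]")
  structure(list(p_w = p_w, x = x), class = "telo_werner")
}

#' Bundle of models defining one simulation case
#'
#' @param loss A [loss_model()].
#' @param division A [division_model()].
#' @param werner A [werner_params()]; default is normal aging.
#' @param threshold Critical telomere length in basepairs: an individual is
#'   senescent when any telomere end is strictly below it.  Default 200.
#' @param werner_floor Feasibility floor for Werner deletions: a deletion
#'   leaving any telomere at the deleted end below this length is
#'   infeasible and the division is blocked.  Defaults to `threshold`.
#' @return An object of class `telo_models`.
#' @export
model_set <- function(loss, division, werner = werner_params(0, 0),
                      threshold = 200, werner_floor = threshold) {
  stopifnot(inherits(loss, "telo_loss"), inherits(division, "telo_division"),
            inherits(werner, "telo_werner"),
            is.numeric(threshold), length(threshold) == 1L, threshold >= 0,
            is.numeric(werner_floor), length(werner_floor) == 1L,
            werner_floor >= 0)
  structure(list(loss = loss, division = division, werner = werner,
                 threshold = threshold, werner_floor = werner_floor),
            class = "telo_models")
}

# Parameter table for the named cases.  All A/B cases share the division
# offset/slope a = -200/5750, b = 1/5750 (P_div = ((n - 200)/5750)^alpha);
# with alpha = 0 (cases A) the probability is identically 1.
.case_table <- list(
  A1        = list(alpha = 0,    y0 = 200,   y1 = 0),
  A2        = list(alpha = 0,    y0 = 100,   y1 = 1 / 30),
  "B1.1"    = list(alpha = 0.25, y0 = 240,   y1 = 0),
  "B1.2"    = list(alpha = 0.5,  y0 = 288,   y1 = 0),
  "B1.3"    = list(alpha = 0.75, y0 = 345,   y1 = 0),
  "B1.4"    = list(alpha = 1,    y0 = 414,   y1 = 0),
  "B2.1"    = list(alpha = 0.25, y0 = 120,   y1 = 1 / 25),
  "B2.2"    = list(alpha = 0.5,  y0 = 144,   y1 = 1 / 21),
  "B2.3"    = list(alpha = 0.75, y0 = 172.5, y1 = 1 / 17),
  "B2.4"    = list(alpha = 1,    y0 = 207,   y1 = 1 / 14),
  zhang_fit = list(alpha = 0.25, y0 = 10,    y1 = 0.043,
                   a = -0.03, b = 1 / 12200, init = 12200)
)

#' Names of the built-in simulation cases
#'
#' @return Character vector of preset names accepted by [preset_case()].
#' @export
case_names <- function() names(.case_table)

#' Built-in simulation cases
#'
#' Returns the full parameter bundle for one of the named shortening cases:
#' `"A1"`, `"A2"` (constant division probability), `"B1.1"`--`"B1.4"`
#' (constant loss, length-dependent division), `"B2.1"`--`"B2.4"` (both
#' length-dependent), or `"zhang_fit"`, the cell-model parameterization
#' fitted to published fibroblast telomere data (loss `10 + 0.043 n`,
#' division probability `(n/12200 - 0.03)^0.25`, initial length 12,200 bp).
#'
#' All A/B cases are calibrated so that the expected loss per replication,
#' `P_div(n) * y(n)`, is approximately 200 bp when half-way to senescence.
#'
#' @param name One of [case_names()].
#' @param threshold Senescence threshold in bp (default 200).
#' @return A [model_set()] with attributes `case` (the preset name) and
#'   `initial_length` (the conventional starting telomere length in bp).
#' @export
#' @examples
#' preset_case("B2.4")$loss$y1 # 1/14
preset_case <- function(name, threshold = 200) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(.case_table))
    stop("unknown case '", name, "'; valid cases: ",
         paste(names(.case_table), collapse = ", "))
  p <- .case_table[[name]]
  a <- if (is.null(p[["a"]])) -200 / 5750 else p[["a"]]
  b <- if (is.null(p[["b"]])) 1 / 5750 else p[["b"]]
  ms <- model_set(loss = loss_model(p[["y0"]], p[["y1"]]),
                  division = division_model(a, b, p[["alpha"]]),
                  threshold = threshold)
  attr(ms, "case") <- name
  attr(ms, "initial_length") <- if (is.null(p[["init"]])) 6000 else p[["init"]]
  ms
}

.werner_table <- data.frame(
  p_w = c(0, 0.2, 0.4, 0.6, 0.8, 1),
  x   = c(0, 1000, 500, 333, 250, 200)
)

#' Standard Werner's-syndrome parameter pairs
#'
#' The deletion size `x` paired with each studied deletion probability
#' `p_w`, chosen so that the expected extra loss `x * p_w` is (close to)
#' 200 bp per replication in every case except normal aging
#' (`p_w = x = 0`).  Arbitrary pairs can still be built directly with
#' [werner_params()].
#'
#' @param p_w One of 0, 0.2, 0.4, 0.6, 0.8, 1.
#' @return A [werner_params()] object.
#' @export
#' @examples
#' preset_werner(0.2)$x # 1000
preset_werner <- function(p_w) {
  stopifnot(is.numeric(p_w), length(p_w) == 1L)
  i <- which(abs(.werner_table$p_w - p_w) < 1e-9)
  if (length(i) != 1L)
    stop("`p_w` must be one of ",
         paste(.werner_table$p_w, collapse = ", "),
         "; construct other pairs with werner_params()")
  werner_params(.werner_table$p_w[i], .werner_table$x[i])
}

#' Table of the standard Werner parameter pairs
#' @return Data frame with columns `p_w` and `x`.
#' @export
werner_table <- function() .werner_table

#' @export
print.telo_models <- function(x, ...) {
  cs <- attr(x, "case")
  cat("telomere model set", if (!is.null(cs)) paste0("(case ", cs, ")"), "\n")
  cat(sprintf("  loss:      y(n) = %g + %g n\n", x$loss$y0, x$loss$y1))
  cat(sprintf("  division:  P(n) = (%g + %g n)^%g\n",
              x$division$a, x$division$b, x$division$alpha))
  cat(sprintf("  werner:    p_w = %g, x = %g bp\n", x$werner$p_w, x$werner$x))
  cat(sprintf("  threshold: %g bp\n", x$threshold))
  invisible(x)
}
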