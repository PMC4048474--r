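# Chromosome-level replication rules.
#
# A chromosome is represented by its four telomere lengths, one per strand
# end, stored as (top_left, top_right, bottom_left, bottom_right).  The row
# convention carries strand orientation: the complement synthesized on the
# "top" strand is incompletely replicated at the RIGHT end, the complement
# of the "bottom" strand at the LEFT end.  A parent in the canonical state
# (m, n / m, n - y) therefore yields one daughter identical to the parent
# and one daughter (m - y, n - y / m, n - y).

#' Chromosome telomere quartet
#'
#' @param top_left,top_right,bottom_left,bottom_right Telomere lengths in
#'   basepairs (real-valued, >= 0).  Alternatively pass a single numeric
#'   vector of length 4 as `top_left`.
#' @return Numeric vector of length 4 with class `telo_quartet`, ordered
#'   `(top_left, top_right, bottom_left, bottom_right)`.
#' @export
#' @examples
#' chromosome_quartet(6000, 6000, 6000, 5800)
chromosome_quartet <- function(top_left, top_right = NULL,
                               bottom_left = NULL, bottom_right = NULL) {
  q <- if (is.null(top_right) && length(top_left) == 4L) as.numeric(top_left)
       else c(top_left, top_right, bottom_left, bottom_right)
  if (length(q) != 4L || !is.numeric(q) || any(!is.finite(q)) || any(q < 0))
    stop("a quartet is four finite non-negative telomere lengths")
  structure(as.numeric(q),
            names = c("top_left", "top_right", "bottom_left", "bottom_right"),
            class = "telo_quartet")
}

as_quartet <- function(q) {
  if (inherits(q, "telo_quartet")) q else chromosome_quartet(q)
}

#' Mean telomere length of a chromosome
#'
#' @param chrom A [chromosome_quartet()] (or plain length-4 vector).
#' @return Arithmetic mean of the four telomere lengths, in bp.
#' @export
#' @examples
#' chromosome_mean_length(chromosome_quartet(6000, 6000, 6000, 5800)) # 5950
chromosome_mean_length <- function(chrom) {
  mean(unclass(as_quartet(chrom)))
}

#' Is a chromosome senescent?
#'
#' A chromosome is senescent when its shortest telomere has fallen strictly
#' below the critical length; a telomere exactly at the threshold may still
#' support division.
#'
#' @param chrom A [chromosome_quartet()].
#' @param threshold Critical length in bp (>= 0).
#' @return Logical flag.
#' @export
is_senescent <- function(chrom, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  min(unclass(as_quartet(chrom))) < threshold
}

#' Normal-aging chromosome replication
#'
#' Implements the end-replication rule: each parent strand templates a new
#' complement that is incompletely replicated at one end, losing `y(n)`
#' basepairs where `n` is the current length of the telomere being eroded.
#' For a parent in the canonical state `(m, n / m, n - y)` this produces
#' one daughter identical to the parent and one shorter daughter
#' `(m - y, n - y / m, n - y)`.  New entries clamp at zero.
#'
#' @param chrom Parent [chromosome_quartet()] (caller ensures it is
#'   non-senescent).
#' @param loss A [loss_model()].
#' @return List with elements `identical` (daughter keeping the top-strand
#'   template) and `shorter` (daughter keeping the bottom-strand template),
#'   both quartets.
#' @export
#' @examples
#' p <- chromosome_quartet(6000, 6000, 6000, 5800)
#' replicate_normal(p, loss_model(200))
replicate_normal <- function(chrom, loss) {
  q <- unclass(as_quartet(chrom))
  y_top <- loss_y(q[2L], loss)
  y_bot <- loss_y(q[3L], loss)
  if (y_top < 0 || y_bot < 0) stop("loss model predicts a negative loss")
  list(
    identical = chromosome_quartet(q[1L], q[2L], q[1L], max(q[2L] - y_top, 0)),
    shorter   = chromosome_quartet(max(q[3L] - y_bot, 0), q[4L], q[3L], q[4L])
  )
}

#' Sample replication events
#'
#' Draws the per-chromosome replication event used in a Werner's-syndrome
#' simulation: with probability `1 - p_w` replication is normal, otherwise
#' one of the four extra-deletion variants is chosen uniformly
#' (unconditional probability `p_w / 4` each).  Consumes the R random
#' stream: one uniform draw per event plus one per Werner event.
#'
#' @param n Number of events to draw.
#' @param p_w Probability of an extra deletion, in `[0, 1]`.
#' @return Integer vector of length `n`: 0 for normal replication, 1--4 for
#'   the deletion variants (see [replicate_werner()]).
#' @export
sample_replication_event <- function(n, p_w) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.numeric(p_w) || length(p_w) != 1L || is.na(p_w) ||
      p_w < 0 || p_w > 1)
    stop("`p_w` must be a probability in [0, 1]")
  n <- as.integer(n)
  ev <- integer(n)
  if (n == 0L) return(ev)
  if (p_w > 0) {
    w <- stats::runif(n) < p_w
    nw <- sum(w)
    if (nw > 0L) ev[w] <- as.integer(floor(stats::runif(nw) * 4)) + 1L
  }
  ev
}

#' Werner's-syndrome chromosome replication
#'
#' One replication attempt in which an extra block of `x` basepairs is
#' deleted at one of four strand/end positions:
#' \describe{
#'   \item{variant 1}{right end of both strands of the daughter keeping the
#'     top template (canonical outcome `(m, n-x / m, n-x-y)`);}
#'   \item{variant 2}{left end of that daughter (`(m-x, n / m-x, n-y)`);}
#'   \item{variant 3}{right end of the daughter keeping the bottom template
#'     (`(m-y, n-x-y / m, n-x-y)`);}
#'   \item{variant 4}{left end of that daughter, the end-replication loss
#'     compounding with the deletion (`(m-x-y, n-y / m-x, n-y)`).}
#' }
#' If any telomere at the deleted end would fall below the feasibility
#' `floor` the attempt is infeasible and the parent remains undivided.  The
#' ordinary `y` loss is evaluated at the length of the telomere being
#' eroded (after the deletion, where the deletion hits the template being
#' copied) and clamps at zero as in normal aging.  With `x = 0` every
#' variant reduces exactly to [replicate_normal()].
#'
#' @param chrom Parent [chromosome_quartet()] (non-senescent).
#' @param loss A [loss_model()].
#' @param x Extra deletion size in bp (>= 0).
#' @param variant Integer 1--4.
#' @param floor Feasibility floor in bp (default 0; the population engine
#'   uses the senescence threshold).
#' @return A division outcome: list with `divided` (flag), `daughters`
#'   (list `identical`/`shorter` as in [replicate_normal()], present iff
#'   divided) and `parent`.
#' @export
replicate_werner <- function(chrom, loss, x, variant, floor = 0) {
  q <- unclass(as_quartet(chrom))
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x >= 0)
  if (!is.numeric(variant) || length(variant) != 1L || !variant %in% 1:4)
    stop("`variant` must be an integer in 1..4")
  stopifnot(is.numeric(floor), length(floor) == 1L, floor >= 0)
  tl <- q[1L]; tr <- q[2L]; bl <- q[3L]; br <- q[4L]

  # normal-aging daughters (deletion-free ends clamp at zero)
  ident <- c(tl, tr, tl, max(tr - loss_y(tr, loss), 0))
  short <- c(max(bl - loss_y(bl, loss), 0), br, bl, br)
  feasible <- TRUE
  if (x > 0) {
    if (variant == 1L) {
      cmpl <- tr - x - loss_y(max(tr - x, 0), loss)
      feasible <- tr - x >= floor && cmpl >= floor
      ident <- c(tl, tr - x, tl, cmpl)
    } else if (variant == 2L) {
      feasible <- tl - x >= floor
      ident <- c(tl - x, tr, tl - x, max(tr - loss_y(tr, loss), 0))
    } else if (variant == 3L) {
      feasible <- br - x >= floor
      short <- c(max(bl - loss_y(bl, loss), 0), br - x, bl, br - x)
    } else {
      cmpl <- bl - x - loss_y(max(bl - x, 0), loss)
      feasible <- bl - x >= floor && cmpl >= floor
      short <- c(cmpl, br, bl - x, br)
    }
  }
  if (!feasible)
    return(list(divided = FALSE, daughters = NULL,
                parent = chromosome_quartet(q)))
  list(divided = TRUE,
       daughters = list(identical = chromosome_quartet(ident),
                        shorter = chromosome_quartet(short)),
       parent = chromosome_quartet(q))
}
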