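# Age-indexed background mortality: synthetic Gompertz-Makeham generator and
# a reader/writer for delimited life-table files.

#' Construct a life table
#'
#' @param qx numeric vector of annual death probabilities for integer ages
#'   \code{0, 1, ..., length(qx) - 1}. Each must lie in \[0, 1\] and the last
#'   entry must equal 1 (absorbing terminal age).
#' @return An object of class \code{life_table} with fields \code{qx} and
#'   \code{max_age}.
#' @export
life_table <- function(qx) {
  if (!is.numeric(qx) || length(qx) < 2 || anyNA(qx))
    stop("qx must be a numeric vector of length >= 2 without NA",
         call. = FALSE)
  if (any(qx < 0 | qx > 1))
    stop("qx out of range: all values must lie in [0, 1]", call. = FALSE)
  if (qx[length(qx)] != 1)
    stop("qx at max_age must equal 1 (absorbing terminal age)",
         call. = FALSE)
  structure(list(qx = as.numeric(qx), max_age = length(qx) - 1L),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages 0-%d; q(0)=%.4g; e0=%.1f y\n",
              x$max_age, x$qx[1], life_expectancy(x)))
  invisible(x)
}

#' Synthetic US-like life table
#'
#' Generates a period life table from a Gompertz-Makeham hazard with an
#' infant-mortality excess at age 0:
#' \deqn{q(x) = 1 - \exp\{-(a + b c^x + \mathrm{infant}\cdot[x=0])\}}
#' The default constants are fixed calibration values (not fitted at
#' runtime) chosen so that period life expectancy at birth is about 78.7
#' years and survival to age 60 about 0.89, emulating recent US all-cause
#' mortality. The table is sex-averaged.
#'
#' @param makeham_a age-independent background hazard per year (>= 0).
#' @param gompertz_b senescent hazard scale per year (>= 0).
#' @param gompertz_c annual senescent hazard growth factor (> 1).
#' @param infant_excess additional first-year hazard (>= 0).
#' @param max_age terminal age; \code{q(max_age)} is set to 1.
#' @return A \code{life_table}.
#' @export
#' @examples
#' lt <- synth_life_table()
#' life_expectancy(lt)
synth_life_table <- function(makeham_a = 5e-4, gompertz_b = 3.5e-5,
                             gompertz_c = 1.095, infant_excess = 5.5e-3,
                             max_age = 110) {
  if (makeham_a < 0 || gompertz_b < 0 || infant_excess < 0)
    stop("hazard parameters must be >= 0", call. = FALSE)
  if (gompertz_c <= 1) stop("gompertz_c must be > 1", call. = FALSE)
  if (max_age < 80) stop("max_age must be >= 80", call. = FALSE)
  age <- 0:max_age
  hazard <- makeham_a + gompertz_b * gompertz_c^age +
    infant_excess * (age == 0)
  qx <- 1 - exp(-hazard)
  qx[max_age + 1] <- 1
  life_table(qx)
}

#' Annual death probability at a given age
#'
#' Integer-age lookup with floor convention; ages above the table's terminal
#' age return 1.
#'
#' @param table a \code{life_table}.
#' @param age age in years (>= 0; may be fractional or a vector).
#' @return Annual death probability (vectorized over \code{age}).
#' @export
annual_mortality <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  a <- pmin(floor(age), table$max_age)
  table$qx[a + 1]
}

#' Survival curve and life expectancy
#'
#' \code{survival_curve} returns \eqn{l(x) = \prod_{t<x}(1-q_t)} for ages 0
#' through \code{max_age} (so \code{l(0) = 1}); \code{life_expectancy}
#' returns the standard period estimate \eqn{e_0 = \sum_{x \ge 1} l(x) + 0.5}
#' (deaths mid-interval on average).
#'
#' @param table a \code{life_table}.
#' @return Numeric vector (survival) or scalar (life expectancy).
#' @export
survival_curve <- function(table) {
  stopifnot(inherits(table, "life_table"))
  cumprod(c(1, 1 - table$qx))[seq_len(table$max_age + 1L)]
}

#' @rdname survival_curve
#' @export
life_expectancy <- function(table) {
  lx <- survival_curve(table)
  sum(lx[-1]) + 0.5
}

#' Read a life table from a delimited file
#'
#' Expects comma-delimited text with a header line naming the two columns
#' \code{age} and \code{qx}; lines starting with \code{#} are comments. Ages
#' must be contiguous integers from 0 and the last row's \code{qx} must be 1.
#'
#' @param path file path.
#' @return A \code{life_table}.
#' @seealso [write_life_table()]
#' @export
load_life_table <- function(path) {
  if (!file.exists(path))
    stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!identical(sort(names(df)), c("age", "qx")))
    stop("life table must have a header with exactly the columns 'age,qx'",
         call. = FALSE)
  df <- df[order(df$age), , drop = FALSE]
  if (!isTRUE(all.equal(df$age, seq(0, nrow(df) - 1))))
    stop("non-contiguous ages: life table ages must run 0,1,2,... ",
         "without gaps", call. = FALSE)
  life_table(df$qx)
}

#' Write a life table to a delimited file
#'
#' @param table a \code{life_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  df <- data.frame(age = 0:table$max_age,
                   qx = format(table$qx, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
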