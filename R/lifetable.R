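#' Synthetic background-mortality lifetable (Gompertz-Makeham)
#'
#' Annual probability of death from causes unrelated to poisoning, for
#' integer ages 0-99 (half-open age intervals `[a, a+1)`). The hazard is
#' Gompertz-Makeham, `h(a) = A + B * exp(C * a)`, converted to an annual
#' probability `q(a) = 1 - exp(-h(a))`. The defaults give a life expectancy
#' at birth of about 81.7 years with plausibly low child mortality; they are
#' a synthetic stand-in for a national lifetable, which is why the packaged
#' fixture is named `lifetable_synthetic.tsv`. Any user lifetable in the
#' same two-column format can be substituted via [read_lifetable()].
#'
#' @param makeham_a Age-independent hazard component (>= 0).
#' @param gompertz_b Senescent hazard scale (>= 0); `gompertz_b = 0` gives a
#'   constant hazard (geometric survival).
#' @param gompertz_c Senescent hazard log-slope per year of age.
#' @param max_age Highest age included (default 99).
#' @return A data.frame with columns `age` (integer) and `qx` (annual death
#'   probability in `[0, 1)`).
#' @examples
#' lt <- make_lifetable()
#' life_expectancy(lt)
#' @export
make_lifetable <- function(makeham_a = 2e-4, gompertz_b = 3e-5,
                           gompertz_c = 0.09, max_age = 99) {
  if (makeham_a < 0 || gompertz_b < 0)
    stop("hazard parameters must be >= 0", call. = FALSE)
  age <- 0:max_age
  qx <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * age)))
  if (any(qx >= 1))
    stop("hazard parameters give death probability >= 1 at some age",
         call. = FALSE)
  data.frame(age = age, qx = qx)
}

#' Read a lifetable from a two-column text file
#'
#' Expects whitespace- or tab-delimited columns `age` (0-based integers,
#' consecutive from 0) and `qx` (annual death probability).
#' @param path File path.
#' @return A validated lifetable data.frame.
#' @export
read_lifetable <- function(path) {
  lt <- utils::read.table(path, header = TRUE)
  validate_lifetable(lt)
}

#' @rdname read_lifetable
#' @param lifetable A lifetable data.frame.
#' @export
validate_lifetable <- function(lifetable) {
  stopifnot(is.data.frame(lifetable),
            all(c("age", "qx") %in% names(lifetable)))
  lt <- lifetable[order(lifetable$age), c("age", "qx")]
  if (!identical(as.integer(lt$age), seq.int(0L, nrow(lt) - 1L)))
    stop("lifetable ages must be consecutive integers starting at 0",
         call. = FALSE)
  if (any(lt$qx < 0 | lt$qx >= 1))
    stop("lifetable death probabilities must lie in [0, 1)", call. = FALSE)
  lt
}

#' The lifetable packaged with the model
#'
#' Loads `inst/extdata/lifetable_synthetic.tsv` (generated by
#' [make_lifetable()] with its default parameters).
#' @return A lifetable data.frame.
#' @export
default_lifetable <- function() {
  read_lifetable(system.file("extdata", "lifetable_synthetic.tsv",
                             package = "poisoncea", mustWork = TRUE))
}

#' Life expectancy at birth implied by a lifetable
#' @param lifetable A lifetable data.frame (`age`, `qx`).
#' @return Expected years lived before the table's end age.
#' @export
life_expectancy <- function(lifetable) {
  lt <- validate_lifetable(lifetable)
  sum(cumprod(1 - lt$qx))
}
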