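## Vegetation-index registry. Indices are algebraic combinations of the four
## per-ROI band means; the registry is data-driven (name -> formula CSV) so
## alternative formulations can be swapped in without code changes. The
## default registry ships 21 standard four-band indices, including the three
## the screening stage typically favours per growth stage: NDVI, RVI and
## OSAVI (soil-adjustment term 0.16).

# Division with a small-denominator guard: |denominator| < eps yields the
# undefined-value sentinel NA rather than +/-Inf, keeping downstream
# correlation code well-defined.
safeDiv <- function(num, den, eps = 1e-9) {
  ifelse(abs(den) < eps, NA_real_, num / den)
}

#' Define a vegetation index
#'
#' @param name unique index name.
#' @param formula a string expression over the band means `green`, `red`,
#'   `red_edge`, `nir` and numeric constants (`sqrt` allowed).
#' @return a `vi_definition` list.
#' @export
viDefinition <- function(name, formula) {
  vars <- all.vars(str2lang(formula))
  unknown <- setdiff(vars, bandNames())
  if (length(unknown))
    stop("formula for ", name, " references unknown band(s): ",
         paste(unknown, collapse = ", "))
  structure(list(name = name, formula = formula), class = "vi_definition")
}

#' The default 21-entry vegetation-index registry
#'
#' Loads the index table shipped in `inst/extdata/vi_registry.csv`.
#'
#' @param path optional path to an alternative registry CSV with columns
#'   `name` and `formula`.
#' @return a named list of `vi_definition` objects, in file order.
#' @examples
#' length(defaultViRegistry())
#' @export
defaultViRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vi_registry.csv", package = "waveCanopy",
                        mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("duplicate index names in registry")
  defs <- lapply(seq_len(nrow(df)),
                 function(i) viDefinition(df$name[i], df$formula[i]))
  names(defs) <- df$name
  defs
}

#' Evaluate one vegetation index
#'
#' Divisions inside the formula are guarded: a denominator with magnitude
#' below 1e-9 yields `NA` (the undefined-value sentinel) rather than
#' infinity.
#'
#' @param defn a `vi_definition`.
#' @param means named reflectances for `green`, `red`, `red_edge`, `nir`.
#' @return the scalar index value, or `NA` when undefined.
#' @examples
#' computeVi(viDefinition("NDVI", "(nir - red)/(nir + red)"),
#'           c(green = 0.1, red = 0.1, red_edge = 0.3, nir = 0.5))
#' @export
computeVi <- function(defn, means) {
  vars <- all.vars(str2lang(defn$formula))
  missing <- setdiff(vars, names(means))
  if (length(missing))
    stop("missing band(s) for ", defn$name, ": ",
         paste(missing, collapse = ", "))
  env <- new.env(parent = baseenv())
  for (b in names(means)) assign(b, unname(means[[b]]), envir = env)
  assign("/", safeDiv, envir = env)
  val <- eval(str2lang(defn$formula), env)
  if (!is.finite(val)) NA_real_ else val
}

#' Evaluate every index in a registry
#'
#' @param registry a list of `vi_definition`s (see [defaultViRegistry()]).
#' @param means named band-mean reflectances.
#' @return a named numeric vector, one entry per registry definition in
#'   registry order; undefined values propagate as `NA`, never dropped.
#' @export
computeAllVis <- function(registry, means) {
  vapply(registry, computeVi, numeric(1), means = means)
}
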