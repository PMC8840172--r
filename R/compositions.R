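#' @keywords internal
"_PACKAGE"

# Component naming conventions used throughout the package.
# Macronutrients are reported in g/kg dry matter, micronutrients in mg/kg.
# All clr arithmetic is done with every part on the g/kg scale so that the
# filling value (Fv) closes the composition to the 1000 g/kg measurement unit.
.macros <- c("N", "P", "K", "Ca", "Mg")
.micros <- c("Cu", "Fe", "Mn", "Zn", "B")
.parts  <- c(.macros, .micros, "Fv")

#' Nutrient component names
#'
#' Component naming used by the compositional machinery: five macronutrients
#' (g/kg), five micronutrients (mg/kg), and the filling value `Fv` (g/kg)
#' that closes each foliar composition to the 1000 g/kg measurement unit.
#'
#' @param which one of `"all"`, `"macro"`, `"micro"`.
#' @return Character vector of component names.
#' @export
#' @examples
#' nutrient_components()
nutrient_components <- function(which = c("all", "macro", "micro")) {
  which <- match.arg(which)
  switch(which, all = .parts, macro = .macros, micro = .micros)
}

#' Filling value of a foliar composition
#'
#' The filling value `Fv` is the unquantified remainder of tissue dry matter:
#' the difference between the 1000 g/kg measurement unit and the sum of the
#' quantified nutrients (micronutrients converted from mg/kg to g/kg). It is
#' carried as an ordinary composition part so that the clr transform operates
#' on a complete composition.
#'
#' @param macros numeric vector or 5-column matrix/data.frame of N, P, K, Ca,
#'   Mg concentrations in g/kg dry matter.
#' @param micros numeric vector or 5-column matrix/data.frame of Cu, Fe, Mn,
#'   Zn, B concentrations in mg/kg dry matter.
#' @return Numeric vector of filling values in g/kg, one per specimen.
#' @export
#' @examples
#' compute_filling_value(c(30, 3, 25, 18, 4), c(6, 80, 90, 30, 35))
compute_filling_value <- function(macros, micros) {
  macros <- .as_row_matrix(macros, 5L, "macros")
  micros <- .as_row_matrix(micros, 5L, "micros")
  if (nrow(macros) != nrow(micros))
    stop("macros and micros must describe the same specimens")
  if (any(macros < 0) || any(micros < 0))
    stop("nutrient concentrations must be non-negative")
  quantified <- rowSums(macros) + rowSums(micros) / 1000
  if (any(quantified >= 1000))
    stop("quantified nutrients sum to >= 1000 g/kg: impossible composition")
  1000 - quantified
}

.as_row_matrix <- function(x, ncol, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) %% ncol != 0L)
      stop(sprintf("%s must have %d components per specimen", what, ncol))
    x <- matrix(x, ncol = ncol, byrow = TRUE)
  }
  if (ncol(x) != ncol)
    stop(sprintf("%s must have %d columns", what, ncol))
  storage.mode(x) <- "double"
  x
}

# Assemble the 11-part composition matrix with every part in g/kg.
# `comp` is a data.frame/matrix with macro columns (g/kg), micro columns
# (mg/kg) and optionally Fv; Fv is derived when absent.
.parts_gkg <- function(comp) {
  comp <- as.data.frame(comp)
  missing_cols <- setdiff(c(.macros, .micros), names(comp))
  if (length(missing_cols))
    stop("missing nutrient columns: ", paste(missing_cols, collapse = ", "))
  macros <- as.matrix(comp[.macros])
  micros <- as.matrix(comp[.micros])
  fv <- if ("Fv" %in% names(comp)) comp[["Fv"]] else
    compute_filling_value(macros, micros)
  parts <- cbind(macros, micros / 1000, Fv = fv)
  colnames(parts) <- .parts
  parts
}

#' Centered log-ratio transform of foliar compositions
#'
#' Each of the 11 parts (5 macronutrients, 5 micronutrients, filling value),
#' expressed in g/kg, is divided by the geometric mean of all 11 parts and
#' logged: `clr_i = ln(x_i / G)`. The resulting vector sums to zero.
#'
#' @param comp data.frame (or matrix) with columns `N,P,K,Ca,Mg` in g/kg and
#'   `Cu,Fe,Mn,Zn,B` in mg/kg; an `Fv` column is used if present and derived
#'   with [compute_filling_value()] otherwise.
#' @return data.frame of clr values with columns `clr_N, ..., clr_Fv` and an
#'   attribute `"G"` holding the per-specimen geometric mean (g/kg).
#' @seealso [clr_inverse()], [replace_zeros()]
#' @export
#' @examples
#' comp <- data.frame(N = 30, P = 3, K = 25, Ca = 18, Mg = 4,
#'                    Cu = 6, Fe = 80, Mn = 90, Zn = 30, B = 35)
#' rowSums(clr_transform(comp))  # ~0
clr_transform <- function(comp) {
  parts <- .parts_gkg(comp)
  if (any(parts <= 0))
    stop("all composition parts must be strictly positive; ",
         "run replace_zeros() on components below detection first")
  lx <- log(parts)
  clr <- lx - rowMeans(lx)
  out <- as.data.frame(clr)
  names(out) <- paste0("clr_", .parts)
  attr(out, "G") <- exp(rowMeans(lx))
  out
}

#' Inverse clr transform with closure
#'
#' Back-transforms clr values to concentrations: parts are exponentiated and
#' rescaled (closed) so that the 11 parts sum to the measurement unit
#' (1000 g/kg by default). `clr_transform(clr_inverse(v))` returns `v` to
#' within 1e-9.
#'
#' @param clr numeric vector of length 11, or a matrix/data.frame with 11
#'   columns, of clr values ordered as [nutrient_components()].
#' @param unit_total measurement unit the composition is closed to (g/kg).
#' @return data.frame with macro columns in g/kg, micro columns in mg/kg and
#'   `Fv` in g/kg (all scaled so the g/kg parts sum to `unit_total`).
#' @export
#' @examples
#' clr_inverse(rep(0, 11))  # 11 equal parts of 1000/11
clr_inverse <- function(clr, unit_total = 1000) {
  if (unit_total <= 0) stop("unit_total must be positive")
  if (is.data.frame(clr)) clr <- as.matrix(clr)
  if (is.null(dim(clr))) clr <- matrix(clr, nrow = 1L)
  if (ncol(clr) != length(.parts))
    stop("clr input must have ", length(.parts), " components")
  s <- rowSums(clr)
  if (any(abs(s) > 1e-6)) {
    warning("clr values do not sum to 0; renormalizing by subtracting the mean")
    clr <- clr - s / ncol(clr)
  }
  ex <- exp(clr)
  parts <- ex / rowSums(ex) * unit_total
  out <- as.data.frame(parts)
  names(out) <- .parts
  out[.micros] <- out[.micros] * 1000  # back to mg/kg for reporting
  out
}

#' Replace below-detection zeros in a composition
#'
#' clr arithmetic requires strictly positive parts. Zeros (values below the
#' detection limit recorded as 0) are replaced by `fraction` times the
#' component's detection limit, and the non-zero parts are multiplicatively
#' rescaled so each specimen's total mass is preserved.
#'
#' @param comp data.frame with the 10 nutrient columns (and optionally `Fv`).
#' @param detection_limits named numeric vector of detection limits in each
#'   component's own unit (g/kg for macros, mg/kg for micros).
#' @param fraction multiplier applied to the detection limit, in (0, 1).
#' @return `comp` with zeros replaced and totals preserved.
#' @export
replace_zeros <- function(comp, detection_limits, fraction = 0.65) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (any(detection_limits <= 0)) stop("detection limits must be positive")
  comp <- as.data.frame(comp)
  nut <- c(.macros, .micros)
  x <- as.matrix(comp[nut])
  if (all(x == 0)) stop("all parts are zero: not a composition")
  zero_cols <- nut[apply(x == 0, 2, any)]
  missing_dl <- setdiff(zero_cols, names(detection_limits))
  if (length(missing_dl))
    stop("zero values with no detection limit for: ",
         paste(missing_dl, collapse = ", "))
  if (!length(zero_cols)) return(comp)
  # work on the common g/kg scale so mass bookkeeping is coherent
  gkg <- x
  gkg[, .micros] <- gkg[, .micros] / 1000
  dl <- detection_limits[zero_cols]
  dl[zero_cols %in% .micros] <- dl[zero_cols %in% .micros] / 1000
  for (i in seq_len(nrow(gkg))) {
    zi <- gkg[i, ] == 0
    if (!any(zi)) next
    repl <- fraction * dl[match(nut[zi], zero_cols)]
    total <- sum(gkg[i, ])
    gkg[i, !zi] <- gkg[i, !zi] * (total - sum(repl)) / total
    gkg[i, zi] <- repl
  }
  gkg[, .micros] <- gkg[, .micros] * 1000
  comp[nut] <- gkg
  comp
}

#' Organic matter from Walkley-Black carbon
#'
#' Converts oxidizable soil carbon to organic matter content with the
#' conventional van Bemmelen factor of 1.724.
#'
#' @param total_C total carbon in g/kg.
#' @return organic matter in g/kg.
#' @export
#' @examples
#' organic_matter_from_carbon(12.18)  # ~21 g/kg
organic_matter_from_carbon <- function(total_C) {
  if (any(total_C < 0)) stop("carbon content cannot be negative")
  1.724 * total_C
}

#' Read a foliar nutrient table
#'
#' Comma-separated text, one row per specimen, with headers
#' `N,P,K,Ca,Mg` (g/kg) and `Cu,Fe,Mn,Zn,B` (mg/kg). A `comma_decimal`
#' flag converts decimal commas on input.
#'
#' @param path file path.
#' @param comma_decimal logical; `TRUE` if the file uses "," as the decimal
#'   separator.
#' @return data.frame of concentrations.
#' @export
read_foliar <- function(path, comma_decimal = FALSE) {
  dec <- if (comma_decimal) "," else "."
  sep <- if (comma_decimal) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(.macros, .micros), names(df))
  if (length(missing_cols))
    stop("foliar table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write a foliar table with derived filling value and clr columns
#'
#' @param comp foliar data.frame as accepted by [clr_transform()].
#' @param path output file path (CSV, "." decimal).
#' @return the augmented data.frame, invisibly.
#' @export
write_foliar <- function(comp, path) {
  comp <- as.data.frame(comp)
  if (!"Fv" %in% names(comp))
    comp$Fv <- compute_filling_value(comp[.macros], comp[.micros])
  out <- cbind(comp, clr_transform(comp))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
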