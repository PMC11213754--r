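#' Construct an elemental formula for a polymer repeat unit
#'
#' Represents a repeat-unit composition CxHyOzNdSe with its molar mass.
#' The molar mass uses integer atomic masses (C 12, H 1, O 16, N 14,
#' S 32). Note that some printed forms of the per-gram Buswell methane
#' potential show a coefficient of 12 for oxygen in the molar-mass
#' denominator; that is a typographical error — only 16 reproduces the
#' standard tabulated potentials (e.g. 0.74 L/g for polycaprolactone).
#'
#' @param x,y,z,d,e Non-negative integer atom counts for C, H, O, N, S.
#'   At least one carbon is required.
#' @return An object of class `elemental_formula`: a list with fields
#'   `x`, `y`, `z`, `d`, `e` and the derived molar mass `Mr` (g/mol).
#' @examples
#' f <- elemental_formula(6, 10, 2) # polycaprolactone repeat unit
#' f$Mr # 114
#' @seealso [parse_formula()], [buswell()], [bmp_theoretical()], [thod()]
#' @export
elemental_formula <- function(x, y = 0, z = 0, d = 0, e = 0) {
  counts <- c(x = x, y = y, z = z, d = d, e = e)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  counts <- round(counts)
  if (counts[["x"]] < 1) {
    stop("formula must contain at least one carbon atom", call. = FALSE)
  }
  mr <- sum(counts * ATOMIC_MASS[c("C", "H", "O", "N", "S")])
  structure(
    list(x = counts[["x"]], y = counts[["y"]], z = counts[["z"]],
         d = counts[["d"]], e = counts[["e"]], Mr = mr),
    class = "elemental_formula"
  )
}

#' @export
format.elemental_formula <- function(x, ...) {
  sym <- c("C", "H", "O", "N", "S")
  n <- unlist(x[c("x", "y", "z", "d", "e")])
  part <- ifelse(n == 0, "", ifelse(n == 1, sym, paste0(sym, n)))
  paste0(paste(part, collapse = ""), " (Mr = ", x$Mr, " g/mol)")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format(x), "\n")
  invisible(x)
}

#' Parse a chemical formula string
#'
#' Accepts repeat-unit formulas over the elements C, H, O, N and S,
#' e.g. `"C6H10O2"`. Each element may appear at most once; an omitted
#' count means 1. Parentheses, hydrates and charges are not supported:
#' polymers are given as their repeat-unit formula.
#'
#' @param text A single formula string. Spaces and underscores are
#'   ignored, so `"C_6_H_10_O_2_"` also parses.
#' @return An [elemental_formula()] object.
#' @examples
#' parse_formula("C2H4") # polyethylene repeat unit
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  s <- gsub("[ _]", "", text)
  if (!nzchar(s)) stop("empty formula string", call. = FALSE)
  tokens <- regmatches(s, gregexpr("[A-Za-z][0-9]*", s))[[1]]
  if (sum(nchar(tokens)) != nchar(s)) {
    stop("cannot parse formula '", text,
         "': unexpected characters", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", tokens)
  bad <- setdiff(el, c("C", "H", "O", "N", "S"))
  if (length(bad)) {
    stop("unknown element symbol '", bad[[1]], "' in formula '", text,
         "' (supported: C, H, O, N, S)", call. = FALSE)
  }
  if (anyDuplicated(el)) {
    stop("element '", el[duplicated(el)][[1]],
         "' appears more than once in formula '", text, "'", call. = FALSE)
  }
  num <- sub("^[A-Za-z]", "", tokens)
  n <- ifelse(num == "", 1L, suppressWarnings(as.integer(num)))
  counts <- stats::setNames(integer(5), c("C", "H", "O", "N", "S"))
  counts[el] <- n
  elemental_formula(counts[["C"]], counts[["H"]], counts[["O"]],
                    counts[["N"]], counts[["S"]])
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

#' Buswell stoichiometric coefficients
#'
#' Balances the anaerobic mineralization of one mole of CxHyOzNdSe with
#' water into methane, carbon dioxide, ammonia and hydrogen sulfide
#' (the Buswell equation):
#'
#' CxHyOzNdSe + (x - y/4 - z/2 + 3d/4 + e/2) H2O ->
#'   (x/2 + y/8 - z/4 - 3d/8 - e/4) CH4 +
#'   (x/2 - y/8 + z/4 + 3d/8 + e/4) CO2 + d NH3 + e H2S
#'
#' Carbon is conserved exactly: `ch4 + co2 == x`.
#'
#' @param f An [elemental_formula()] or a formula string.
#' @return An object of class `buswell_coefficients`: list with fields
#'   `water`, `ch4`, `co2`, `nh3`, `h2s` (mol per mol of repeat unit)
#'   and logical `methane_positive`. A formula too oxidized to yield
#'   methane (`ch4 <= 0`) is flagged with a warning, not an error.
#' @examples
#' buswell("C6H10O2") # ch4 = 3.75, co2 = 2.25
#' @export
buswell <- function(f) {
  f <- as_formula(f)
  x <- f$x; y <- f$y; z <- f$z; d <- f$d; e <- f$e
  out <- structure(
    list(
      water = x - y / 4 - z / 2 + 3 * d / 4 + e / 2,
      ch4 = x / 2 + y / 8 - z / 4 - 3 * d / 8 - e / 4,
      co2 = x / 2 - y / 8 + z / 4 + 3 * d / 8 + e / 4,
      nh3 = d,
      h2s = e,
      methane_positive = TRUE
    ),
    class = "buswell_coefficients"
  )
  if (out$ch4 <= 0) {
    out$methane_positive <- FALSE
    warning("formula ", format(f),
            " is too oxidized to yield methane (ch4 coefficient <= 0)",
            call. = FALSE)
  }
  out
}

#' @export
print.buswell_coefficients <- function(x, ...) {
  cat("<buswell_coefficients>\n")
  cat(sprintf("  H2O %+g  ->  CH4 %g, CO2 %g, NH3 %g, H2S %g\n",
              x$water, x$ch4, x$co2, x$nh3, x$h2s))
  if (!x$methane_positive) cat("  [flag] no net methane yield\n")
  invisible(x)
}

#' Theoretical biochemical methane potential (BMP)
#'
#' Maximum methane yield from complete anaerobic mineralization of a
#' polymer, in litres of CH4 at STP (0 degC, 1 atm; 22.4 L/mol) per
#' gram of polymer: `22.4 * ch4 / Mr`, with `ch4` the Buswell methane
#' coefficient. Values are returned at full precision; round only at
#' report time.
#'
#' @inheritParams buswell
#' @return Numeric scalar, L CH4 (STP) per g polymer.
#' @examples
#' round(bmp_theoretical("C2H4"), 2) # 1.20 (polyethylene)
#' round(bmp_theoretical("C6H10O2"), 2) # 0.74 (polycaprolactone)
#' @export
bmp_theoretical <- function(f) {
  f <- as_formula(f)
  b <- buswell(f)
  MOLAR_VOLUME_STP * b$ch4 / f$Mr
}

#' Theoretical oxygen demand (ThOD)
#'
#' Mass of O2 required for complete aerobic mineralization of a
#' carbon/hydrogen/oxygen polymer CcHhOo, in grams of O2 per gram of
#' polymer: `(31.9988 / Mr) * (c + 0.25 h - 0.5 o)`. The formula is
#' defined for C/H/O compounds only; nitrogen or sulfur raise an error.
#'
#' @inheritParams buswell
#' @return Numeric scalar, g O2 per g polymer.
#' @examples
#' round(thod("C2H4"), 2) # 3.43 (polyethylene)
#' @export
thod <- function(f) {
  f <- as_formula(f)
  if (f$d > 0 || f$e > 0) {
    stop("theoretical oxygen demand is defined for C/H/O formulas only; ",
         format(f), " contains N or S", call. = FALSE)
  }
  (O2_MOLAR_MASS / f$Mr) * (f$x + 0.25 * f$y - 0.5 * f$z)
}

#' Theoretical degradation potentials for one polymer
#'
#' Convenience bundle of [bmp_theoretical()] and [thod()] for a single
#' repeat-unit formula. ThOD is `NA` for formulas containing N or S.
#'
#' @inheritParams buswell
#' @return Object of class `theoretical_potentials`: list with
#'   `formula`, `bmp_theoric` (L CH4 STP per g) and `thod` (g O2 per g).
#' @export
theoretical_potentials <- function(f) {
  f <- as_formula(f)
  structure(
    list(
      formula = f,
      bmp_theoric = bmp_theoretical(f),
      thod = if (f$d == 0 && f$e == 0) thod(f) else NA_real_
    ),
    class = "theoretical_potentials"
  )
}

#' @export
print.theoretical_potentials <- function(x, ...) {
  cat("<theoretical_potentials>", format(x$formula), "\n")
  cat(sprintf("  BMP_theoric: %.4f L CH4 (STP) / g\n", x$bmp_theoric))
  if (is.na(x$thod)) cat("  ThOD: not defined (formula contains N or S)\n")
  else cat(sprintf("  ThOD: %.4f g O2 / g\n", x$thod))
  invisible(x)
}

#' Read a polymer registry
#'
#' A registry is a JSON array of `{name, formula}` records. The package
#' ships presets for PE, PET, PCL and the cellulose monomer under
#' `system.file("extdata", "polymers.json", package = "biodeg")`.
#'
#' @param path Path to a registry JSON file; `NULL` loads the shipped
#'   presets.
#' @return Named character vector of formulas, names are polymer names.
#' @export
read_polymer_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "polymers.json", package = "biodeg")
  }
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("name", "formula") %in% names(reg))) {
    stop("registry must contain 'name' and 'formula' fields", call. = FALSE)
  }
  stats::setNames(as.character(reg$formula), as.character(reg$name))
}

#' Tabulate theoretical potentials for a set of polymers
#'
#' @param polymers Named character vector of formulas (names are polymer
#'   labels), e.g. from [read_polymer_registry()].
#' @param digits Decimal places for the reported potentials (default 2,
#'   the conventional reporting precision; internal values stay at full
#'   precision).
#' @return A data.frame with columns `name`, `formula`, `Mr`,
#'   `bmp_theoric_l_g`, `thod_g_g`.
#' @examples
#' potentials_table(c(PE = "C2H4", PCL = "C6H10O2"))
#' @export
potentials_table <- function(polymers, digits = 2) {
  rows <- lapply(seq_along(polymers), function(i) {
    f <- parse_formula(polymers[[i]])
    data.frame(
      name = names(polymers)[i],
      formula = polymers[[i]],
      Mr = f$Mr,
      bmp_theoric_l_g = round(bmp_theoretical(f), digits),
      thod_g_g = if (f$d == 0 && f$e == 0) round(thod(f), digits)
                 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
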