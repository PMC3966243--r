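#' Physiological constants of the PTH distribution and clearance system
#'
#' Container for the fixed whole-body constants: plasma flows through the
#' clearing organs, their extraction fractions, compartment volumes and the
#' serum/interstitial exchange rate. Defaults are the human values the model
#' was built with.
#'
#' @param renal_flow Renal plasma flow (L/min). Default 0.625.
#' @param hepatic_flow Hepatic plasma flow (L/min). Default 1.02.
#' @param renal_extraction Renal single-pass extraction fraction of PTH
#'   (dimensionless, in (0,1)). Default 0.34.
#' @param hepatic_extraction Hepatic single-pass extraction fraction.
#'   Default 0.44.
#' @param serum_volume Serum (plasma) volume (L). Default 3.
#' @param isf_volume Interstitial fluid volume (L). Default 11.
#' @param exchange_fraction Fraction of the serum–interstitial concentration
#'   difference exchanged per minute (1/min). Default 0.5. The exchange mass
#'   flux is referenced to the serum volume (see
#'   `vignette("pth-population-model")`); the model is insensitive to this
#'   convention.
#'
#' @return An object of class `physio_constants` (a named list).
#' @seealso [clearance_constant()]
#' @examples
#' pc <- physio_constants()
#' clearance_constant(pc)
#' @export
physio_constants <- function(renal_flow = 0.625,
                             hepatic_flow = 1.02,
                             renal_extraction = 0.34,
                             hepatic_extraction = 0.44,
                             serum_volume = 3,
                             isf_volume = 11,
                             exchange_fraction = 0.5) {
  x <- list(
    renal_flow = renal_flow, hepatic_flow = hepatic_flow,
    renal_extraction = renal_extraction,
    hepatic_extraction = hepatic_extraction,
    serum_volume = serum_volume, isf_volume = isf_volume,
    exchange_fraction = exchange_fraction
  )
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("physio_constants: '", nm, "' must be a single positive number")
  }
  if (renal_extraction >= 1 || hepatic_extraction >= 1)
    stop("physio_constants: extraction fractions must lie in (0, 1)")
  structure(x, class = "physio_constants")
}

#' Whole-body PTH clearance constant
#'
#' Composes renal and hepatic clearance as flow times extraction:
#' `k_cl = renal_flow * renal_extraction + hepatic_flow * hepatic_extraction`
#' (L/min). With the default constants this is
#' 0.625*0.34 + 1.02*0.44 = 0.6613 L/min.
#'
#' @param constants A [physio_constants()] object.
#' @return Clearance in L/min (single number).
#' @export
clearance_constant <- function(constants = physio_constants()) {
  stopifnot(inherits(constants, "physio_constants"))
  constants$renal_flow * constants$renal_extraction +
    constants$hepatic_flow * constants$hepatic_extraction
}

#' @export
print.physio_constants <- function(x, ...) {
  cat("Physiological constants:\n")
  cat(sprintf("  renal flow        %6.3f L/min (extraction %.2f)\n",
              x$renal_flow, x$renal_extraction))
  cat(sprintf("  hepatic flow      %6.3f L/min (extraction %.2f)\n",
              x$hepatic_flow, x$hepatic_extraction))
  cat(sprintf("  serum volume      %6.2f L\n", x$serum_volume))
  cat(sprintf("  interstitial vol  %6.2f L\n", x$isf_volume))
  cat(sprintf("  exchange fraction %6.2f /min\n", x$exchange_fraction))
  cat(sprintf("  => clearance k_cl %6.4f L/min\n", clearance_constant(x)))
  invisible(x)
}

#' Read physiological-constant overrides from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys mirror the
#' [physio_constants()] argument names; listed fields override the
#' defaults, unlisted fields keep them.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [physio_constants()] object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML constants requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(physio_constants))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown constant field(s): ", paste(bad, collapse = ", "))
  do.call(physio_constants, vals)
}
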