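# Dinucleotide physicochemical lookup tables.

.DINUCLEOTIDES <- c("AA", "AC", "AG", "AU",
                    "CA", "CC", "CG", "CU",
                    "GA", "GC", "GG", "GU",
                    "UA", "UC", "UG", "UU")

.FREE_ENERGY <- c(
  AA = -0.930, AC = -2.240, AG = -2.080, AU = -1.100,
  CA = -2.110, CC = -3.260, CG = -2.360, CU = -2.080,
  GA = -2.350, GC = -3.420, GG = -3.260, GU = -2.240,
  UA = -1.330, UC = -2.350, UG = -2.110, UU = -0.930)

.HYDROPHILICITY <- c(
  AA = 0.040, AC = 0.140, AG = 0.080, AU = 0.140,
  CA = 0.210, CC = 0.490, CG = 0.350, CU = 0.520,
  GA = 0.100, GC = 0.260, GG = 0.170, GU = 0.270,
  UA = 0.210, UC = 0.480, UG = 0.340, UU = 0.440)

#' Dinucleotide physicochemical property table
#'
#' Returns the lookup used to turn an RNA sequence into numeric profiles:
#' for each of the 16 dinucleotides over \{A, C, G, U\}, the stacking free
#' energy (kcal/mol) and the hydrophilicity value. These are the standard
#' published dinucleotide constants for RNA (e.g. free energy of GG is
#' -3.260, hydrophilicity of CU is 0.520).
#'
#' @return A named list with elements \code{free_energy} and
#'   \code{hydrophilicity}, each a named numeric vector of length 16 keyed
#'   by dinucleotide.
#' @examples
#' tab <- dinucleotide_properties()
#' tab$free_energy[["GG"]]
#' @export
dinucleotide_properties <- function() {
  list(free_energy = .FREE_ENERGY, hydrophilicity = .HYDROPHILICITY)
}

# Validate a (possibly user-supplied) property table.
check_property_table <- function(table, property) {
  if (!property %in% names(table)) {
    stop("unknown property '", property, "'; available: ",
         paste(names(table), collapse = ", "), call. = FALSE)
  }
  vals <- table[[property]]
  missing <- setdiff(.DINUCLEOTIDES, names(vals))
  if (length(missing) > 0) {
    stop("property table '", property, "' is missing dinucleotides: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals
}
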