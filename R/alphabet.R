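# Nucleobase alphabet, pairing table, and idealized atomic templates.
#
# The code alphabet covers the canonical bases (A, T, G, C, U), the
# fluorescent analogs 2-aminopurine (E) and tricyclic cytosine (D), the
# Hachimoji set (B, S, Z, P) and the hydrophobic pair d5SICS (L) / dNaM (M).
# Atomic templates are shipped for the canonical bases only; the extended
# codes are supported at sequence/frame bookkeeping level.

BASE_ALPHABET <- c("A", "T", "G", "C", "U", "E", "D", "B", "S", "Z", "P", "L", "M")

# Single-valued complement map.  Hachimoji pairs are taken as B-S and P-Z;
# the fluorescent tricyclic cytosine D pairs with G.  U and E pair into the
# canonical strand (A and T respectively), so the map is an involution only
# on the subset excluding U, E and D.
COMPLEMENT_MAP <- c(A = "T", T = "A", G = "C", C = "G", U = "A",
                    E = "T", D = "G",
                    B = "S", S = "B", Z = "P", P = "Z",
                    L = "M", M = "L")

PURINE_CODES <- c("A", "G", "E", "B", "Z")   # glycosidic nitrogen N9
RESNAME_MAP <- c(A = "DA", T = "DT", G = "DG", C = "DC", U = "DU")
# methylated variants keep their own residue codes on output
METHYL_RESNAME <- c(C = "5CM", G = "7MG")

#' Complement a sequence over the extended nucleobase alphabet
#'
#' Per-position complement (A-T, G-C, U->A, 2-aminopurine->T, tricyclic
#' cytosine->G, Hachimoji B-S and P-Z, d5SICS-dNaM), returned 5'->3' on the
#' complementary strand, i.e. reversed.
#'
#' @param sequence Character string over the code alphabet.
#' @return Complementary sequence, 5'->3'.
#' @examples
#' complement("GGAA")  # "TTCC"
#' @export
complement <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  bad <- which(!ch %in% BASE_ALPHABET)
  if (length(bad))
    stop("unknown base code at position(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(ch[bad]), collapse = ""))
  paste(rev(unname(COMPLEMENT_MAP[ch])), collapse = "")
}

# per-position (unreversed) complement characters
complement_chars <- function(chars) unname(COMPLEMENT_MAP[chars])

#' Nucleobase alphabet
#'
#' @return Character vector of the supported single-letter base codes.
#' @export
base_alphabet <- function() BASE_ALPHABET

# ---------------------------------------------------------------------------
# Idealized planar base templates in the standard base reference frame.
# Coordinates in nm; x toward the major groove, y toward the reference
# strand backbone, z along the helix axis; base atoms lie in the z = 0
# plane.  Heavy atoms of the base plus the glycosidic C1' carbon.  These are
# idealized fixture geometries: no sugar ring or phosphate is modeled, which
# is a documented limitation of the atomic output.

base_template_table <- function() {
  A <- matrix(c(
    -0.2479, 0.5346, 0,   # C1'
    -0.1291, 0.4498, 0,   # N9
     0.0024, 0.4897, 0,   # C8
     0.0877, 0.3902, 0,   # N7
     0.0071, 0.2771, 0,   # C5
     0.0369, 0.1398, 0,   # C6
     0.1611, 0.0909, 0,   # N6
    -0.0668, 0.0532, 0,   # N1
    -0.1912, 0.1023, 0,   # C2
    -0.2320, 0.2290, 0,   # N3
    -0.1267, 0.3124, 0),  # C4
    ncol = 3, byrow = TRUE)
  rownames(A) <- c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")

  G <- matrix(c(
    -0.2477, 0.5399, 0,
    -0.1289, 0.4551, 0,
     0.0023, 0.4962, 0,
     0.0870, 0.3969, 0,
     0.0071, 0.2833, 0,
     0.0424, 0.1460, 0,
     0.1554, 0.0955, 0,
    -0.0700, 0.0641, 0,
    -0.1999, 0.1087, 0,
    -0.2949, 0.0139, 0,
    -0.2342, 0.2364, 0,
    -0.1265, 0.3177, 0),
    ncol = 3, byrow = TRUE)
  rownames(G) <- c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")

  C <- matrix(c(
    -0.2477, 0.5402, 0,
    -0.1285, 0.4542, 0,
    -0.1472, 0.3158, 0,
    -0.2628, 0.2709, 0,
    -0.0391, 0.2344, 0,
     0.0837, 0.2868, 0,
     0.1875, 0.2027, 0,
     0.1056, 0.4275, 0,
    -0.0023, 0.5068, 0),
    ncol = 3, byrow = TRUE)
  rownames(C) <- c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")

  T <- matrix(c(
    -0.2481, 0.5354, 0,
    -0.1284, 0.4500, 0,
    -0.1462, 0.3135, 0,
    -0.2562, 0.2608, 0,
    -0.0298, 0.2407, 0,
     0.0994, 0.2897, 0,
     0.1944, 0.2119, 0,
     0.1106, 0.4338, 0,
     0.2466, 0.4961, 0,
    -0.0024, 0.5057, 0),
    ncol = 3, byrow = TRUE)
  rownames(T) <- c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")

  U <- matrix(c(
    -0.2481, 0.5354, 0,
    -0.1284, 0.4500, 0,
    -0.1462, 0.3131, 0,
    -0.2563, 0.2608, 0,
    -0.0302, 0.2397, 0,
     0.0989, 0.2884, 0,
     0.1935, 0.2094, 0,
     0.1089, 0.4311, 0,
    -0.0024, 0.5053, 0),
    ncol = 3, byrow = TRUE)
  rownames(U) <- c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")

  list(A = A, G = G, C = C, T = T, U = U)
}

.template_env <- new.env(parent = emptyenv())

#' Atomic template for a base code
#'
#' Templates are expressed in the standard base reference frame (template
#' frame = identity), coordinates in nm.  Canonical codes A, T, G, C, U are
#' shipped; other codes are bookkeeping-only and raise unless a user
#' template has been registered with [register_base_template()].
#'
#' @param code Single-letter base code.
#' @return List with `code`, `atoms` (named coordinate matrix, nm),
#'   `elements`, `glycosidic_atoms` (C1' and the glycosidic nitrogen) and
#'   `ring_atoms` (names used for frame fitting).
#' @export
base_template <- function(code) {
  if (!is.null(.template_env[[code]])) return(.template_env[[code]])
  tab <- base_template_table()
  if (!code %in% names(tab))
    stop("no atomic template for base code '", code,
         "' (bookkeeping-only; register one with register_base_template())")
  atoms <- tab[[code]]
  gly_n <- if (code %in% PURINE_CODES) "N9" else "N1"
  ring <- if (code %in% PURINE_CODES)
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else
    c("N1", "C2", "N3", "C4", "C5", "C6")
  list(code = code,
       atoms = atoms,
       elements = substr(rownames(atoms), 1, 1),
       glycosidic_atoms = c("C1'", gly_n),
       ring_atoms = ring)
}

#' Register a user-supplied atomic base template
#'
#' @param code Base code (may be non-canonical).
#' @param atoms Named coordinate matrix (rows = atom names), nm, in the
#'   standard base reference frame.
#' @param glycosidic_atoms Length-2 atom-name vector defining the glycosidic
#'   bond.
#' @param ring_atoms Atom names used for frame fitting.
#' @return Invisibly, the stored template.
#' @export
register_base_template <- function(code, atoms, glycosidic_atoms, ring_atoms) {
  stopifnot(is.matrix(atoms), ncol(atoms) == 3, !is.null(rownames(atoms)))
  tpl <- list(code = code, atoms = atoms,
              elements = substr(rownames(atoms), 1, 1),
              glycosidic_atoms = glycosidic_atoms, ring_atoms = ring_atoms)
  assign(code, tpl, envir = .template_env)
  invisible(tpl)
}

has_template <- function(code) {
  !is.null(.template_env[[code]]) || code %in% names(base_template_table())
}
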