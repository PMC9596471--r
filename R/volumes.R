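# Amino-acid volume table and the four volume groups used by the AAG
# encoding: minuscule {G,A,S,C}, small {T,D,P,N,V},
# intermediate {E,Q,H,L,I,M,K}, large {R,F,Y,W}.

AA_GROUPS <- c(
  G = "minuscule", A = "minuscule", S = "minuscule", C = "minuscule",
  T = "small", D = "small", P = "small", N = "small", V = "small",
  E = "intermediate", Q = "intermediate", H = "intermediate",
  L = "intermediate", I = "intermediate", M = "intermediate",
  K = "intermediate",
  R = "large", F = "large", Y = "large", W = "large"
)
GROUP_LEVELS <- c("minuscule", "small", "intermediate", "large")

#' Load an amino-acid volume table
#'
#' Reads a residue-volume table (tab-separated, columns `residue` and
#' `volume_A3`, `#` comment lines allowed) and attaches the four-way volume
#' group of each residue. With no `path` the bundled Zamyatnin residue-volume
#' table is used; any table with the same format can be swapped in.
#'
#' @param path Optional path to a TSV file with columns
#'   `residue` and `volume_A3`. `NULL` (default) loads the bundled table.
#' @return An object of class `volume_table`: a data frame with columns
#'   `residue`, `volume_A3` and `group`, one row per proteinogenic residue.
#' @export
#' @examples
#' tab <- load_volume_table()
#' tab[tab$residue == "G", ]
load_volume_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_volumes.tsv", package = "subnanospec",
                        mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "volume_A3") %in% names(df)))
    stop("volume table must have columns 'residue' and 'volume_A3'")
  df$residue <- toupper(trimws(df$residue))
  dup <- df$residue[duplicated(df$residue)]
  if (length(dup))
    stop(sprintf("duplicate residue %s in volume table", dup[1L]))
  miss <- setdiff(AA_ALPHABET, df$residue)
  if (length(miss))
    stop(sprintf("missing residue %s in volume table", miss[1L]))
  extra <- setdiff(df$residue, AA_ALPHABET)
  if (length(extra))
    stop(sprintf("unknown residue %s in volume table", extra[1L]))
  bad <- df$residue[!is.finite(df$volume_A3) | df$volume_A3 <= 0]
  if (length(bad))
    stop(sprintf("non-positive volume for residue %s", bad[1L]))
  df <- df[match(AA_ALPHABET, df$residue), , drop = FALSE]
  df$group <- factor(AA_GROUPS[df$residue], levels = GROUP_LEVELS)
  gm <- tapply(df$volume_A3, df$group, mean)
  if (any(diff(gm[GROUP_LEVELS]) <= 0))
    stop("volume groups are not ordered: group mean volumes must increase ",
         "from minuscule to large")
  rownames(df) <- df$residue
  class(df) <- c("volume_table", "data.frame")
  df
}

#' Residue volumes for a peptide
#'
#' Maps each residue of a peptide to its volume.
#'
#' @param peptide Peptide string.
#' @param table A `volume_table` from [load_volume_table()].
#' @return Numeric vector of volumes (one per residue).
#' @export
peptide_volumes <- function(peptide, table = load_volume_table()) {
  res <- peptide_residues(peptide)
  unname(table[res, "volume_A3"])
}
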