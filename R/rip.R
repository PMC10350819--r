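#' One RIP replicate at one temperature
#'
#' Holds the four measured quantities of an RNA-immunoprecipitation
#' replicate: target mRNA in input and in the pulldown (relative RNA
#' units), and the immunoprecipitated protein in input and pulldown
#' (densitometry units).
#'
#' @param replicate Replicate identifier.
#' @param temperature `"37C"` or `"32C"` (free text allowed).
#' @param target_input_rna,target_ip_rna Relative target-mRNA quantities in
#'   input and IP fractions (> 0).
#' @param protein_input,protein_ip Immunoprecipitated-protein densitometry
#'   in input and IP fractions (> 0).
#' @return A `rip_measurement` object.
#' @export
rip_measurement <- function(replicate, temperature, target_input_rna,
                            target_ip_rna, protein_input, protein_ip) {
  vals <- c(target_input_rna, target_ip_rna, protein_input, protein_ip)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all RIP quantities must be finite and > 0")
  structure(list(replicate = replicate, temperature = temperature,
                 target_input_rna = target_input_rna,
                 target_ip_rna = target_ip_rna,
                 protein_input = protein_input, protein_ip = protein_ip),
            class = "rip_measurement")
}

#' Normalized RIP fold change on cooling
#'
#' The raw change in pulled-down target mRNA between temperatures is
#' confounded by any change in total target mRNA and in pulldown efficiency
#' of the protein itself. Both are divided out:
#' \deqn{FC = \frac{ip_{32}/ip_{37}}{input_{32}/input_{37}} \cdot
#'   \frac{1}{\eta_{32}/\eta_{37}}, \qquad
#'   \eta = \frac{protein_{ip}}{protein_{input}}}
#' The result is invariant to independent rescaling of RNA and protein
#' units, and equals 1 when IP enrichment and pulldown efficiency change
#' together.
#'
#' @param m37,m32 [rip_measurement()]s of the same replicate at 37 and 32
#'   degrees C.
#' @return The normalized fold change (single number).
#' @export
rip_fold_change <- function(m37, m32) {
  stopifnot(inherits(m37, "rip_measurement"),
            inherits(m32, "rip_measurement"))
  if (!identical(m37$replicate, m32$replicate))
    stopf("paired measurements must share a replicate id ('%s' vs '%s')",
          m37$replicate, m32$replicate)
  eff37 <- m37$protein_ip / m37$protein_input
  eff32 <- m32$protein_ip / m32$protein_input
  (m32$target_ip_rna / m37$target_ip_rna) /
    (m32$target_input_rna / m37$target_input_rna) /
    (eff32 / eff37)
}

#' RIP fold changes for a replicate table
#'
#' Expects CSV columns `replicate, temperature, target_input_rna,
#' target_ip_rna, protein_input, protein_ip`, with a 37C and a 32C row per
#' replicate.
#'
#' @param path CSV file path.
#' @param warm,cold Temperature labels (defaults `"37C"`, `"32C"`).
#' @return Data frame `replicate, fold_change`.
#' @export
rip_fold_change_table <- function(path, warm = "37C", cold = "32C") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- NULL
  for (r in unique(tab$replicate)) {
    d <- tab[tab$replicate == r, ]
    row <- function(temp) {
      x <- d[d$temperature == temp, ]
      if (nrow(x) != 1L)
        stopf("replicate '%s' needs exactly one row at %s", r, temp)
      rip_measurement(r, temp, x$target_input_rna, x$target_ip_rna,
                      x$protein_input, x$protein_ip)
    }
    out <- rbind(out, data.frame(
      replicate = r, fold_change = rip_fold_change(row(warm), row(cold))))
  }
  rownames(out) <- NULL
  out
}
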