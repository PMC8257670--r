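#' Construct a gene signature
#'
#' A named feature set, optionally signed: `positive` features rise and
#' `negative` features fall with the phenotype. An empty `negative` set
#' makes it an unsigned mean-expression signature.
#'
#' @param name signature name.
#' @param positive,negative disjoint character vectors of feature ids.
#' @param provenance free-text derivation note ("derived", "published",
#'   "synthetic", ...).
#' @param statistics optional per-feature data frame (e.g. Spearman rho
#'   and FDR for derived signatures).
#' @return a `gene_signature` object.
#' @examples
#' gene_signature("toy", positive = c("a", "b"), negative = "c")
#' @export
gene_signature <- function(name, positive, negative = character(0),
                           provenance = "derived", statistics = NULL) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(intersect(positive, negative)))
    stop("positive and negative feature sets must be disjoint")
  if (!length(positive) && !length(negative))
    stop("a signature needs at least one feature")
  structure(list(name = name, positive = positive, negative = negative,
                 provenance = provenance, statistics = statistics),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "' (", x$provenance, ")\n", sep = "")
  cat("  positive (up):  ", length(x$positive), " features\n", sep = "")
  if (length(x$negative))
    cat("  negative (down):", length(x$negative), "features\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$positive) + length(x$negative)

signature_features <- function(sig) c(sig$positive, sig$negative)

#' The published 14-miRNA bladder hypoxia signature
#'
#' The fixed 14-miRNA muscle-invasive bladder cancer hypoxia signature:
#' seven miRNAs positively and seven negatively correlated with an mRNA
#' hypoxia anchor score, with the reported Spearman rho and FDR values
#' attached as per-feature statistics. Scores from this signature are
#' mean(positives) - mean(negatives) on log2 expression.
#'
#' @return a signed [gene_signature()].
#' @examples
#' sig <- published_mirna_signature()
#' sig$statistics
#' @export
published_mirna_signature <- function() {
  stats <- data.frame(
    feature_id = c("miR-27a-3p", "miR-193b-3p", "miR-455-5p", "miR-221-3p",
                   "miR-210-3p", "miR-21-5p", "miR-224-5p",
                   "miR-491-5p", "miR-93-5p", "miR-182-5p", "miR-30b-5p",
                   "miR-190a-5p", "miR-28-5p", "miR-191-5p"),
    rho = c(0.53, 0.35, 0.33, 0.33, 0.30, 0.24, 0.24,
            -0.20, -0.20, -0.21, -0.26, -0.29, -0.29, -0.29),
    fdr = c(0.0, 1.82e-08, 6.57e-08, 7.39e-08, 9.35e-08, 1.00e-06, 8.84e-05,
            1.21e-03, 6.63e-04, 4.50e-04, 1.43e-05, 1.56e-06, 1.56e-06,
            1.56e-06),
    stringsAsFactors = FALSE)
  gene_signature("mirna-hypoxia-14",
                 positive = stats$feature_id[stats$rho > 0],
                 negative = stats$feature_id[stats$rho < 0],
                 provenance = "published", statistics = stats)
}

#' Write signatures to a GMT file
#'
#' Signed signatures are written as two records, `NAME_UP` and
#' `NAME_DN`; unsigned signatures as a single record.
#'
#' @param signatures a [gene_signature()] or list of them.
#' @param path output file.
#' @param description second GMT column (default the provenance).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, description = NULL) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(sig) {
    desc <- if (is.null(description)) sig$provenance else description
    if (length(sig$negative))
      c(paste(c(paste0(sig$name, "_UP"), desc, sig$positive),
              collapse = "\t"),
        paste(c(paste0(sig$name, "_DN"), desc, sig$negative),
              collapse = "\t"))
    else paste(c(sig$name, desc, sig$positive), collapse = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read signatures from a GMT file
#'
#' `NAME_UP`/`NAME_DN` record pairs are reassembled into one signed
#' signature; all other records become unsigned signatures.
#'
#' @param path GMT file path.
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  up <- grepl("_UP$", names(sets))
  dn <- grepl("_DN$", names(sets))
  base_up <- sub("_UP$", "", names(sets)[up])
  base_dn <- sub("_DN$", "", names(sets)[dn])
  signed <- intersect(base_up, base_dn)
  out <- list()
  for (nm in signed)
    out[[nm]] <- gene_signature(nm, positive = sets[[paste0(nm, "_UP")]],
                                negative = sets[[paste0(nm, "_DN")]],
                                provenance = "file")
  plain <- names(sets)[!(up & sub("_UP$", "", names(sets)) %in% signed) &
                         !(dn & sub("_DN$", "", names(sets)) %in% signed)]
  for (nm in plain)
    out[[nm]] <- gene_signature(nm, positive = sets[[nm]], provenance = "file")
  out
}
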