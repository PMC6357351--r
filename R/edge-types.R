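#' @keywords internal
"_PACKAGE"

## The four typed regulation relationships and the node kinds they imply.
EDGE_TYPES <- c("TF_gene", "TF_miRNA", "miRNA_gene", "miRNA_TF")

SOURCE_KIND <- c(TF_gene = "TF", TF_miRNA = "TF",
                 miRNA_gene = "miRNA", miRNA_TF = "miRNA")
TARGET_KIND <- c(TF_gene = "gene", TF_miRNA = "miRNA",
                 miRNA_gene = "gene", miRNA_TF = "TF")

NODE_KINDS <- c("TF", "miRNA", "gene")

#' Edge types recognised by fflnet
#'
#' @return Character vector of the four regulation edge types.
#' @export
edge_types <- function() EDGE_TYPES

check_edge_type <- function(edge_type) {
  if (!is.character(edge_type) || !all(edge_type %in% EDGE_TYPES)) {
    stop("edge_type must be one of: ", paste(EDGE_TYPES, collapse = ", "),
         call. = FALSE)
  }
  edge_type
}

## Derive a per-artifact RNG seed from the global seed so that regenerating
## one artifact (tables vs expression vs gene sets) does not perturb another.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483647)
}
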