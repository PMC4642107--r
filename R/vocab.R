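#' Controlled vocabularies
#'
#' Character vectors defining the closed vocabularies used throughout the
#' package: the five GRN interaction types, the entity types consumed by the
#' entity-type filter, the regulatory layers and bases of the coarse event
#' type, and the regulation family of the GE event-type inventory.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
GRN_TYPES <- c("Binding", "Transcription", "Regulation", "Activation", "Inhibition")

# Gold relation files may additionally contain Requirement edges; the converter
# never produces them, so they always score as deletions.
#' @rdname vocabularies
#' @export
GOLD_RELATION_TYPES <- c(GRN_TYPES, "Requirement")

#' @rdname vocabularies
#' @export
ENTITY_TYPES <- c("Gene", "Protein", "Operon", "PolymeraseComplex",
                  "ProteinComplex", "GGP", "Other")

#' @rdname vocabularies
#' @export
REG_LAYERS <- c("None", "Unspecified", "Positive", "Negative")

#' @rdname vocabularies
#' @export
COARSE_BASES <- c("Binding", "Transcription", "GeneExpression", "Other")

# Regulation family of the GE vocabulary and the regulatory layer each
# member contributes.
REGULATION_FAMILY <- c(Regulation = "Unspecified",
                       Positive_regulation = "Positive",
                       Negative_regulation = "Negative")

# GE event types used for categorical features (anything else falls into an
# "other" bucket).
GE_EVENT_TYPES <- c("Gene_expression", "Transcription", "Localization",
                    "Protein_catabolism", "Phosphorylation",
                    "Protein_modification", "Ubiquitination", "Acetylation",
                    "Deacetylation", "Binding", "Regulation",
                    "Positive_regulation", "Negative_regulation")

#' Event-type groups used in per-group performance breakdowns
#'
#' Groups event types into the four families conventionally reported for GE
#' evaluation: simple events, protein modifications, binding, and the
#' regulation family. Types outside the listed groups fall into `"Other"`.
#'
#' @export
EVENT_TYPE_GROUPS <- list(
  "Simple"       = c("Gene_expression", "Transcription", "Localization"),
  "Protein mod." = c("Phosphorylation", "Protein_modification",
                     "Ubiquitination", "Acetylation", "Deacetylation"),
  "Binding"      = "Binding",
  "Regulation"   = c("Regulation", "Positive_regulation", "Negative_regulation")
)

event_type_group <- function(event_type) {
  for (g in names(EVENT_TYPE_GROUPS)) {
    if (event_type %in% EVENT_TYPE_GROUPS[[g]]) return(g)
  }
  "Other"
}

# All coarse event-type categories (layer, base). Binding base occurs only
# with layer None.
coarse_categories <- function() {
  cats <- c("None|Binding", "None|Other", "None|Transcription",
            "None|GeneExpression")
  for (layer in c("Unspecified", "Positive", "Negative")) {
    for (base in c("Transcription", "GeneExpression", "Other", "Binding")) {
      if (base == "Binding") next
      cats <- c(cats, paste(layer, base, sep = "|"))
    }
  }
  cats
}

#' Compose two regulatory layers
#'
#' Polarity algebra for nested regulation chains: signs multiply
#' (Positive ∘ Negative = Negative, Negative ∘ Negative = Positive) and
#' Unspecified absorbs everything it touches.
#'
#' @param outer,inner regulatory layers, each one of `"Unspecified"`,
#'   `"Positive"`, `"Negative"`.
#' @return the composed layer.
#' @export
compose_layers <- function(outer, inner) {
  stopifnot(outer %in% REG_LAYERS, inner %in% REG_LAYERS)
  if (outer == "Unspecified" || inner == "Unspecified") return("Unspecified")
  if (outer == "None" || inner == "None") stop("cannot compose the empty layer")
  if (outer == inner) "Positive" else "Negative"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fscore <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

safe_div <- function(num, den, empty = 1) if (den == 0) empty else num / den
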