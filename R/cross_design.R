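# Cross designs: which sequenced library plays which role in the recessive
# mapping cross, and which genotype class each role is expected to show.

CROSS_ROLES <- c("affected_parent", "carrier_parent",
                 "affected_pool", "carrier_pool")
AFFECTED_ROLES <- c("affected_parent", "affected_pool")
CARRIER_ROLES  <- c("carrier_parent", "carrier_pool")
PARENT_ROLES   <- c("affected_parent", "carrier_parent")

#' Define a mapping-by-sequencing cross design
#'
#' A design lists the sequenced libraries (parents and pooled offspring) of
#' one or more families of a recessive mono-locus cross, the role each plays,
#' and how genotype expectations are oriented relative to the reference
#' genome.  Under `reference_carries_mutant` (a reference individual
#' heterozygous for the trait allele, the situation in corn-snake Motley
#' mapping) affected samples are expected homozygous *reference* (0/0) at a
#' co-segregating site; under `reference_carries_wildtype` they are expected
#' homozygous *alternate*.  Carrier-role samples are always expected
#' heterozygous.
#'
#' @param samples data frame with columns `sample_id`, `family_id`, `role`;
#'   `role` is one of `"affected_parent"`, `"carrier_parent"`,
#'   `"affected_pool"`, `"carrier_pool"`.  A parent shared between families
#'   (e.g. the same sire sequenced as two libraries) appears once per family
#'   under its own `sample_id`.
#' @param orientation `"reference_carries_mutant"` (default) or
#'   `"reference_carries_wildtype"`.
#' @param missing_policy how a missing (`./.`) genotype in a required sample
#'   is treated when classifying co-segregation: `"fail_variant"` (default,
#'   the variant is not co-segregating) or `"ignore_sample"` (the sample is
#'   dropped from the test for that variant).
#' @return an object of class `cross_design`.
#' @examples
#' d <- cross_design(data.frame(
#'   sample_id = c("sire", "dam", "aff_pool", "carr_pool"),
#'   family_id = "fam1",
#'   role = c("carrier_parent", "affected_parent",
#'            "affected_pool", "carrier_pool")))
#' expected_class("affected_pool", d$orientation)
#' @export
cross_design <- function(samples,
                         orientation = c("reference_carries_mutant",
                                         "reference_carries_wildtype"),
                         missing_policy = c("fail_variant", "ignore_sample")) {
  orientation <- match.arg(orientation)
  missing_policy <- match.arg(missing_policy)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "family_id", "role")
  if (!all(req %in% names(samples)))
    stop("design needs columns: ", paste(req, collapse = ", "))
  samples <- samples[, req]
  samples[] <- lapply(samples, as.character)
  bad <- setdiff(unique(samples$role), CROSS_ROLES)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  for (fam in unique(samples$family_id)) {
    roles <- samples$role[samples$family_id == fam]
    if (!any(roles %in% AFFECTED_ROLES) || !any(roles %in% CARRIER_ROLES))
      stop("family '", fam,
           "' must have at least one affected-role and one carrier-role sample")
  }
  structure(list(samples = samples, orientation = orientation,
                 missing_policy = missing_policy),
            class = "cross_design")
}

#' Read a cross design from a TSV file
#'
#' The file has a header line and columns `sample_id`, `family_id`, `role`.
#'
#' @param path TSV path.
#' @inheritParams cross_design
#' @return a `cross_design`.
#' @export
read_cross_design <- function(path,
                              orientation = "reference_carries_mutant",
                              missing_policy = "fail_variant") {
  cross_design(utils::read.delim(path, stringsAsFactors = FALSE),
               orientation = orientation, missing_policy = missing_policy)
}

#' Families of a design
#' @param design a `cross_design`.
#' @return character vector of family ids.
#' @export
design_families <- function(design) unique(design$samples$family_id)

#' Expected genotype class for a role
#'
#' @param role one of the four cross roles.
#' @param orientation design orientation (see [cross_design()]).
#' @return `"hom_ref"`, `"hom_alt"` or `"het"` (vectorised over `role`).
#' @export
expected_class <- function(role, orientation = "reference_carries_mutant") {
  hom <- if (orientation == "reference_carries_mutant") "hom_ref" else "hom_alt"
  ifelse(role %in% AFFECTED_ROLES, hom,
         ifelse(role %in% CARRIER_ROLES, "het", NA_character_))
}

#' @export
print.cross_design <- function(x, ...) {
  cat("cross_design:", nrow(x$samples), "samples in",
      length(design_families(x)), "family(ies)\n")
  cat("  orientation:", x$orientation,
      "| missing_policy:", x$missing_policy, "\n")
  print(x$samples, row.names = FALSE)
  invisible(x)
}
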