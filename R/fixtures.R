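#' Packaged fixture: the 13-pathway nephrotoxicity AOP inventory
#'
#' The thirteen individual nephrotoxicity AOPs curated from the AOP-Wiki
#' (snapshot of 1 May 2023) with their identifiers, titles, designated
#' molecular initiating events and adverse outcomes. Only the pathway
#' endpoints are part of the public inventory; the interior key events of
#' each pathway live in the full curated relationship table and are therefore
#' represented here by clearly namespaced placeholders
#' (`"placeholder:AOP105:KE1"`), never by invented biology. The Greek alpha
#' of the alpha2u-microglobulin titles is transliterated to ASCII
#' (`"alpha2u"`).
#'
#' Two pathways (437 and 447) share their MIE — inhibition of the
#' mitochondrial electron transport chain complexes — which is the structural
#' hook that connects them in a merged network even before interior events
#' are considered.
#'
#' @return a list of class `aop_fixture` with elements `name`, `records` (an
#'   [aop_collection()]), `expected` (named list of reference values) and
#'   `provenance`.
#' @export
table1_fixture <- function() {
  inv <- tibble::tribble(
    ~aop_id, ~title, ~mie, ~ao,
    105L, "Alpha_2u_-microglobulin cytotoxicity leading to renal tubular adenomas and carcinomas (in male rat)",
    "Increased, binding of chemicals to alpha2u (serum)",
    "Increase, adenomas/carcinomas (renal tubular)",
    116L, "Cytotoxicity leading to renal tubular adenomas and carcinomas (in male rat)",
    "Increase, cytotoxicity (tubular epithelial cells)",
    "Increase, adenomas/carcinomas (renal tubular)",
    138L, "Organic anion transporter (OAT1) inhibition leading to renal failure and mortality",
    "Inhibition, organic anion transporter 1 (OAT1)",
    "Increased mortality and decline, population",
    177L, "Cyclooxygenase 1 (COX1) inhibition leading to renal failure and mortality",
    "Inhibition, cyclooxygenase 1 activity",
    "Increased mortality and decline, population",
    186L, "Unknown MIE leading to renal failure and mortality",
    "Unknown, MIE",
    "Increased mortality",
    256L, "Inhibition of mitochondrial DNA polymerase gamma leading to kidney toxicity",
    "Inhibition of mitochondrial DNA polymerase gamma (Pol gamma)",
    "Occurrence, kidney toxicity",
    257L, "Receptor-mediated endocytosis and lysosomal overload leading to kidney toxicity",
    "Binding of substrate, endocytic receptor",
    "Occurrence, kidney toxicity",
    258L, "Renal protein alkylation leading to kidney toxicity",
    "Alkylation, protein",
    "Occurrence, kidney toxicity",
    284L, "Binding of electrophilic chemicals to SH(thiol)-group of proteins and/or to selenoproteins involved in protection against oxidative stress leads to chronic kidney disease",
    "Binding, thiol proteins/selenoproteins involved in protection against oxidative stress",
    "Chronic kidney disease",
    384L, "Hyperactivation of ACE/Ang-II/AT1R axis leading to chronic kidney disease",
    "Hyperactivation of ACE/Ang-II/AT1R axis",
    "Chronic kidney disease",
    413L, "Oxidation and antagonism of reduced glutathione leading to mortality via acute renal failure",
    "Oxidation, glutathione",
    "Increased kidney failure and mortality",
    437L, "Inhibition of mitochondrial electron transport chain (ETC) complexes leading to kidney toxicity",
    "Inhibition, mitochondrial electron transport chain complexes",
    "Occurrence, kidney toxicity",
    447L, "Kidney failure induced by inhibition of mitochondrial electron transfer chain through apoptosis, inflammation, and oxidative stress pathways",
    "Inhibition, mitochondrial electron transport chain complexes",
    "Increased, kidney failure"
  )
  rows <- lapply(seq_len(nrow(inv)), function(i) {
    mid <- sprintf("placeholder:AOP%d:KE1", inv$aop_id[[i]])
    tibble(
      aop_id = inv$aop_id[[i]],
      aop_title = inv$title[[i]],
      upstream_title = c(inv$mie[[i]], mid),
      upstream_type = c("MIE", "KE"),
      downstream_title = c(mid, inv$ao[[i]]),
      downstream_type = c("KE", "AO"),
      adjacency = "adjacent",
      woe = "unspecified"
    )
  })
  structure(
    list(
      name = "nephrotoxicity_aop_inventory",
      records = aop_collection(bind_rows(rows)),
      expected = list(
        n_aops = 13L,
        aop_ids = inv$aop_id,
        shared_mie = "Inhibition, mitochondrial electron transport chain complexes",
        shared_mie_aops = c(437L, 447L)
      ),
      provenance = "Nephrotoxicity AOP inventory curated from the AOP-Wiki (https://aopwiki.org), snapshot of 1 May 2023; interior key events are placeholders"
    ),
    class = "aop_fixture"
  )
}

#' Packaged fixture: reference convergence/divergence classification
#'
#' The reference lists of convergent (11) and divergent (13) key events of
#' the merged nephrotoxicity AOP network, under the harmonised short titles
#' used in the curated network. Carries no relationship rows — it exists to
#' cross-check [classify_convergence()] once the full curated relationship
#' table is ingested.
#'
#' @return an `aop_fixture`; `expected$convergent` and `expected$divergent`
#'   are tibbles with columns `ke_type`, `ke_name`.
#' @export
table2_fixture <- function() {
  convergent <- tibble::tribble(
    ~ke_type, ~ke_name,
    "KE", "Occurrence, tubular necrosis",
    "MIE/KE", "Increase, cytotoxicity",
    "KE", "Increase, oxidative stress",
    "KE", "Increased sodium-sensitive hypertension",
    "KE/AO", "Increased, kidney failure",
    "KE/AO", "Occurrence, kidney toxicity",
    "KE", "Increase, apoptosis",
    "KE", "Increased blood uric acid concentration",
    "AO", "Chronic kidney disease",
    "AO", "Increased mortality",
    "AO", "Increase, adenomas/carcinomas"
  )
  divergent <- tibble::tribble(
    ~ke_type, ~ke_name,
    "KE", "Increase, Mt dysfunction",
    "KE", "Increased, ROS",
    "KE", "Increase, lipid peroxidation",
    "KE", "Altered NRF2 antioxidant pathway",
    "MIE", "Inhibition, mtETC complexes",
    "MIE", "Alkylation, protein",
    "MIE", "Increased, Binding of chemicals to alpha2u",
    "MIE", "Inhibition, OAT1",
    "MIE", "Binding of substrate endocytic receptor",
    "MIE", "Inhibition of mtDNA (Pol gamma)",
    "MIE", "Binding, thiol proteins/selenoproteins",
    "MIE", "Inhibition, COX1 activity",
    "MIE", "Hyperactivation of ACE/Ang-II, AT1R axis"
  )
  structure(
    list(
      name = "nephrotoxicity_convergence_reference",
      records = aop_collection(tibble(
        aop_id = integer(0), aop_title = character(0),
        upstream_title = character(0), upstream_type = character(0),
        downstream_title = character(0), downstream_type = character(0),
        adjacency = character(0), woe = character(0)
      )),
      expected = list(convergent = convergent, divergent = divergent),
      provenance = "Convergence/divergence classification of the curated nephrotoxicity AOP network (AOP-Wiki snapshot, 1 May 2023)"
    ),
    class = "aop_fixture"
  )
}

#' @export
print.aop_fixture <- function(x, ...) {
  cat(sprintf("<aop_fixture> %s (%s)\n", x$name, x$provenance))
  invisible(x)
}
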