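## Demo "world": gene universes, family tables, ortholog map, toy GO DAG,
## annotations and theme map, all generated with known ground truth.

## Gene universe for one synthetic species. Mouse symbols are title-case,
## human upper-case; pseudogenes follow the "-ps" (mouse) / "AS" (human)
## suffix convention. Three "irregular" pairs break the case rule on
## purpose so that the explicit ortholog map is exercised.
demo_universe <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  rpl <- sprintf("Rpl%d", 1:48)
  rps <- sprintf("Rps%d", 1:32)
  pseudo_parents <- sprintf("Rpl%d", 1:10)
  pseudos <- sprintf("Rpl%d-ps1", 1:10)
  synapse <- sprintf("Syng%02d", 1:30)
  irregular <- c("Irrg1", "Irrg2", "Irrg3")
  decoys <- sprintf("Dcy%04d", seq_len(1077))
  u <- list(
    rpg_large = rpl, rpg_small = rps, rpg = c(rpl, rps),
    planted_rpgs = c(sprintf("Rpl%d", 1:9), sprintf("Rps%d", 1:6)),
    pseudogenes = pseudos, pseudo_parents = pseudo_parents,
    synapse = synapse, irregular = irregular, decoys = decoys
  )
  if (species == "human") {
    u <- lapply(u, toupper)
    u$pseudogenes <- sprintf("RPL%dAS1", 1:10)
    u$irregular <- c("IRRGA", "IRRGB", "IRRGC")
  }
  u$genes <- c(u$rpg, u$pseudogenes, u$synapse, u$irregular, u$decoys)
  u
}

## Toy GO term table and is_a edges shared by both species.
demo_go_terms <- function() {
  terms <- data.frame(
    id = c("GO:0008150", "GO:0010467", "GO:0006412", "GO:0042254",
           "GO:0016441", "GO:0099536", "GO:0007268", "GO:0002376",
           "GO:0045087", "GO:0008152", "GO:0006629", "GO:0007049",
           "GO:0016049"),
    name = c("biological_process", "gene expression", "translation",
             "ribosome biogenesis", "posttranscriptional gene silencing",
             "synaptic signaling", "chemical synaptic transmission",
             "immune system process", "innate immune response",
             "metabolic process", "lipid metabolic process", "cell cycle",
             "cell growth"),
    namespace = "biological_process",
    stringsAsFactors = FALSE
  )
  parents <- list(
    "GO:0010467" = "GO:0008150", "GO:0006412" = "GO:0010467",
    "GO:0042254" = "GO:0010467", "GO:0016441" = "GO:0010467",
    "GO:0099536" = "GO:0008150", "GO:0007268" = "GO:0099536",
    "GO:0002376" = "GO:0008150", "GO:0045087" = "GO:0002376",
    "GO:0008152" = "GO:0008150", "GO:0006629" = "GO:0008152",
    "GO:0007049" = "GO:0008150", "GO:0016049" = "GO:0008150"
  )
  list(terms = terms, parents = parents)
}

## Theme map: keyword route and DAG-descent (anchor) route.
demo_theme_map <- function() {
  list(
    ribosome = list(keywords = c("ribosom", "translation"),
                    anchor_terms = "GO:0006412"),
    synapse = list(keywords = "synap", anchor_terms = "GO:0099536"),
    rna_regulation = list(keywords = c("silencing", "rna"),
                          anchor_terms = "GO:0016441"),
    immune = list(keywords = "immune", anchor_terms = "GO:0002376"),
    metabolism = list(keywords = "metabol", anchor_terms = "GO:0008152")
  )
}

#' Generate the full set of synthetic pipeline fixtures
#'
#' Produces, with known ground truth and at toy scale, every tabular input
#' the pipeline consumes: gene universes for a synthetic mouse and human
#' (1,200 genes each, including an 80-member RPG family split into large-
#' and small-subunit families, 10 RP pseudogenes with species-convention
#' suffixes, a 30-gene synapse block and decoys), an HGNC-style gene-family
#' table with decoy families, a 1:1 ortholog map covering the symbols that
#' break the mouse/human case convention, a rooted acyclic toy GO DAG,
#' per-species gene-to-term annotations, and a theme map with keyword and
#' anchor-term routes.
#'
#' @param seed RNG seed; the same seed yields identical fixtures.
#' @return A list with elements `universes` (per species), `families`
#'   (data.frame `family_id`, `species`, `symbol`), `orthologs`
#'   (data.frame `mouse_symbol`, `human_symbol`), `go` (list `terms`,
#'   `parents`), `annotations` (per-species data.frame `gene`, `term`),
#'   `dags` (per-species [GODag-class]) and `themes` (theme map list).
#' @examples
#' fx <- generateFixtures(seed = 1)
#' head(fx$families)
#' fx$dags$mouse
#' @export
generateFixtures <- function(seed = 1L) {
  with_seed(seed, {
    uni <- list(mouse = demo_universe("mouse"),
                human = demo_universe("human"))
    go <- demo_go_terms()

    fam <- do.call(rbind, lapply(names(uni), function(sp) {
      u <- uni[[sp]]
      rows <- rbind(
        data.frame(family_id = "large_rpg", symbol = u$rpg_large),
        data.frame(family_id = "small_rpg", symbol = u$rpg_small),
        data.frame(family_id = "ribosomal_protein", symbol = u$rpg)
      )
      rows$species <- sp
      rows
    }))
    ## decoy families: same member indices in both species so the family is
    ## genuinely shared cross-species
    n_decoy_fam <- 8L
    sizes <- sample(20:60, n_decoy_fam, replace = TRUE)
    idx <- lapply(sizes, function(s) sample(length(uni$mouse$decoys), s))
    for (f in seq_len(n_decoy_fam)) {
      for (sp in names(uni)) {
        fam <- rbind(fam, data.frame(
          family_id = sprintf("decoy_fam_%02d", f),
          symbol = uni[[sp]]$decoys[idx[[f]]], species = sp
        ))
      }
    }
    fam <- fam[, c("family_id", "species", "symbol")]

    orthologs <- data.frame(
      mouse_symbol = c(uni$mouse$pseudogenes, uni$mouse$irregular),
      human_symbol = c(uni$human$pseudogenes, uni$human$irregular),
      stringsAsFactors = FALSE
    )

    ## annotation blocks: fixed decoy subsets, drawn once per call
    ann_idx <- list(
      immune = sample(length(uni$mouse$decoys), 20),
      lipid = sample(length(uni$mouse$decoys), 25),
      cycle = sample(length(uni$mouse$decoys), 40),
      growth = sample(length(uni$mouse$decoys), 15)
    )
    annotations <- lapply(uni, function(u) {
      rbind(
        data.frame(gene = u$rpg, term = "GO:0006412"),
        data.frame(gene = u$pseudogenes, term = "GO:0016441"),
        data.frame(gene = u$synapse, term = "GO:0007268"),
        data.frame(gene = u$decoys[ann_idx$immune], term = "GO:0045087"),
        data.frame(gene = u$decoys[ann_idx$lipid], term = "GO:0006629"),
        data.frame(gene = u$decoys[ann_idx$cycle], term = "GO:0007049"),
        data.frame(gene = u$decoys[ann_idx$growth], term = "GO:0016049")
      )
    })
    dags <- lapply(annotations, function(ann) {
      goDag(go$terms, go$parents, ann)
    })

    list(universes = uni, families = fam, orthologs = orthologs, go = go,
         annotations = annotations, dags = dags,
         themes = demo_theme_map())
  })
}

#' Default demo simulation design for one synthetic species
#'
#' Encodes the planted-effect world exercised by the end-to-end demo: a
#' 15-gene subset of the 80-member RPG family down-regulated at log2FC -1
#' in the stress group, an anti-correlated 10-gene RP pseudogene block
#' up-regulated at log2FC +1, and a 30-gene synapse module positively
#' loaded (0.8) on the same latent factor as the seed RPGs. Dispersion is
#' 0.1 and each (sex, group) cell has `nPerGroup` samples.
#'
#' @param species `"mouse"` or `"human"`.
#' @param nPerGroup samples per (sex, group) cell (default 20).
#' @param seed RNG seed for the resulting [SimDesign-class].
#' @param planted_lfc log2 fold change planted on the 15 RPGs (default -1);
#'   the pseudogene block is planted at `-planted_lfc`.
#' @param loading latent-factor loading magnitude (default 0.8).
#' @return A [SimDesign-class].
#' @examples
#' demoDesign("mouse", seed = 3)
#' @export
demoDesign <- function(species = c("mouse", "human"), nPerGroup = 20L,
                       seed = 1L, planted_lfc = -1, loading = 0.8) {
  species <- match.arg(species)
  u <- demo_universe(species)
  planted <- c(
    setNames(rep(planted_lfc, length(u$planted_rpgs)), u$planted_rpgs),
    setNames(rep(-planted_lfc, length(u$pseudogenes)), u$pseudogenes)
  )
  modules <- list(
    list(seeds = u$planted_rpgs, members = u$synapse, sign = 1,
         magnitude = loading, latent = "stressmod"),
    list(seeds = character(0), members = u$pseudogenes, sign = -1,
         magnitude = loading, latent = "stressmod")
  )
  simDesign(species = species, genes = u$genes, nPerGroup = nPerGroup,
            planted = planted, modules = modules, seed = seed)
}
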