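## Negative-binomial count simulation with planted effects.

#' Construct a SimDesign
#'
#' @param species species label stored with the samples.
#' @param genes gene universe (unique symbols).
#' @param nPerGroup samples per (sex, group) cell, `>= 2`.
#' @param sexes sex levels (default `c("F", "M")`).
#' @param groups group levels; the first must be `"control"`.
#' @param planted named numeric of log2 fold changes applied to the
#'   non-control group.
#' @param modules list of module specs; see [SimDesign-class]. Entries may
#'   omit `latent` (defaults to the module index) and `seeds`.
#' @param dispersion NB dispersion phi; `0` degenerates to Poisson.
#' @param libSizeRange library sizes are drawn log-uniformly within this
#'   range.
#' @param covariates named numeric of per-covariate gene-coefficient SDs.
#' @param baseMeanLog `c(meanlog, sdlog)` of the log-normal base mean.
#' @param seed RNG seed.
#' @return A validated [SimDesign-class].
#' @examples
#' d <- simDesign(genes = paste0("g", 1:50),
#'                planted = c(g1 = -1, g2 = 1), nPerGroup = 5)
#' d
#' @export
simDesign <- function(species = "mouse",
                      genes,
                      nPerGroup = 20L,
                      sexes = c("F", "M"),
                      groups = c("control", "stress"),
                      planted = numeric(0),
                      modules = list(),
                      dispersion = 0.1,
                      libSizeRange = c(5e5, 2e6),
                      covariates = c(age = 0.3, rin = 0.2),
                      baseMeanLog = c(meanlog = log(80), sdlog = 1.1),
                      seed = 1L) {
  modules <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    m$seeds <- m$seeds %||% character(0)
    m$latent <- m$latent %||% as.character(i)
    m
  })
  new("SimDesign",
      species = species, genes = genes, nPerGroup = as.integer(nPerGroup),
      sexes = sexes, groups = groups, planted = planted, modules = modules,
      dispersion = dispersion, libSizeRange = as.numeric(libSizeRange),
      covariates = covariates, baseMeanLog = baseMeanLog,
      seed = as.integer(seed))
}

#' Simulate a gene-by-sample count matrix from a SimDesign
#'
#' Counts are negative binomial with log-normal gene base means, log-uniform
#' library-size factors, a `2^log2FC` group effect on non-control samples,
#' module structure induced by shared per-sample Gaussian latent factors on
#' the log2-mean scale, and gene-level covariate effects. At dispersion 0
#' the generator degenerates to Poisson.
#'
#' Member genes of a module correlate with its seed genes with the
#' specified sign; two modules sharing a `latent` id share the factor, so a
#' pseudogene block declared with `sign = -1` on its parent module's latent
#' anti-correlates with the parent RPGs.
#'
#' @param design a [SimDesign-class].
#' @return A list with `se`, a [StressCountSet-class] whose `colData`
#'   carries `species`, `sex`, `group` and one column per covariate, and
#'   `truth`, a list with `log2FC` (named over every gene, 0 where null),
#'   `modules` and `baseMean`.
#' @examples
#' d <- simDesign(genes = paste0("g", 1:30), planted = c(g1 = -1),
#'                nPerGroup = 4, seed = 7)
#' sim <- simulateCounts(d)
#' dim(sim$se)
#' @export
simulateCounts <- function(design) {
  stopifnot(is(design, "SimDesign"))
  validObject(design)
  with_seed(design@seed, {
    genes <- design@genes
    G <- length(genes)
    base_mean <- stats::rlnorm(G, design@baseMeanLog[["meanlog"]],
                               design@baseMeanLog[["sdlog"]])
    names(base_mean) <- genes

    layout <- expand.grid(
      i = seq_len(design@nPerGroup), group = design@groups,
      sex = design@sexes, stringsAsFactors = FALSE
    )
    S <- nrow(layout)
    sample_id <- sprintf("%s_%s_%s_%02d", design@species, layout$sex,
                         layout$group, layout$i)

    libsize <- exp(runif(S, log(design@libSizeRange[1]),
                         log(design@libSizeRange[2])))

    eta <- matrix(0, nrow = G, ncol = S, dimnames = list(genes, sample_id))

    is_case <- layout$group != "control"
    if (length(design@planted)) {
      eta[names(design@planted), is_case] <-
        eta[names(design@planted), is_case] + design@planted
    }

    latent_ids <- unique(vapply(design@modules, `[[`, "", "latent"))
    if (length(latent_ids)) {
      z <- matrix(rnorm(S * length(latent_ids)), nrow = S,
                  dimnames = list(sample_id, latent_ids))
      ## standardise the factor within each (sex, group) cell: module
      ## co-expression is variation orthogonal to the planted group
      ## contrasts (the role surrogate variables play on real data); an
      ## uncentred factor would confound the contrast at finite n
      cell <- paste(layout$sex, layout$group)
      for (cl in unique(cell)) {
        i <- cell == cl
        z[i, ] <- scale(z[i, , drop = FALSE])
      }
      for (m in design@modules) {
        zl <- z[, m$latent]
        if (length(m$seeds)) {
          eta[m$seeds, ] <- eta[m$seeds, ] +
            rep(m$magnitude * zl, each = length(m$seeds))
        }
        if (length(m$members)) {
          eta[m$members, ] <- eta[m$members, ] +
            rep(m$sign * m$magnitude * zl, each = length(m$members))
        }
      }
    }

    cov_vals <- NULL
    if (length(design@covariates)) {
      cov_vals <- matrix(rnorm(S * length(design@covariates)), nrow = S,
                         dimnames = list(sample_id,
                                         names(design@covariates)))
      for (cv in names(design@covariates)) {
        coef <- rnorm(G, 0, design@covariates[[cv]])
        eta <- eta + outer(coef, cov_vals[, cv])
      }
    }

    mu <- base_mean * (matrix(rep(libsize, each = G), nrow = G) / 1e6) *
      2^eta
    counts <- if (design@dispersion > 0) {
      rnbinom(G * S, mu = mu, size = 1 / design@dispersion)
    } else {
      rpois(G * S, lambda = mu)
    }
    counts <- matrix(as.integer(counts), nrow = G,
                     dimnames = list(genes, sample_id))

    cd <- data.frame(
      sample_id = sample_id, species = design@species, sex = layout$sex,
      group = layout$group, stringsAsFactors = FALSE
    )
    if (!is.null(cov_vals)) cd <- cbind(cd, as.data.frame(cov_vals))

    log2fc <- setNames(numeric(G), genes)
    if (length(design@planted)) log2fc[names(design@planted)] <-
        design@planted

    list(
      se = StressCountSet(counts, cd),
      truth = list(log2FC = log2fc, modules = design@modules,
                   baseMean = base_mean)
    )
  })
}
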