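#' DNA pool specifications
#'
#' A pool spec records how many nanograms of each species' genomic DNA went
#' into the pooled stock and how much total DNA is drawn into one PCR
#' reaction (20 ng in the experimental design this toolkit mirrors). The
#' per-reaction mass of species s is `reaction_ng * masses[s] / sum(masses)`.
#'
#' @param name pool label (e.g. `"a"`, `"c1"`, `"d"`).
#' @param masses named numeric vector, species -> nanograms in the stock.
#' @param reaction_ng total DNA per PCR reaction (ng).
#' @return a `pool_spec`.
#' @export
#' @examples
#' p <- pool_spec("demo", c(pig = 10, cattle = 100), reaction_ng = 20)
#' per_reaction_ng(p)
pool_spec <- function(name, masses, reaction_ng = 20) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(masses) || is.null(names(masses)) || any(masses <= 0) ||
      anyNA(masses))
    stop("masses must be a named numeric vector of positive nanograms",
         call. = FALSE)
  if (anyDuplicated(names(masses)))
    stop("duplicate species in pool ", name, call. = FALSE)
  stopifnot(reaction_ng > 0)
  structure(list(name = name, masses = masses,
                 reaction_ng = as.numeric(reaction_ng)),
            class = "pool_spec")
}

#' @export
print.pool_spec <- function(x, ...) {
  cat("DNA pool", x$name, "-", length(x$masses), "species,",
      x$reaction_ng, "ng per reaction\n")
  print(per_reaction_ng(x))
  invisible(x)
}

#' Per-reaction DNA mass of each pooled species
#'
#' @param pool a [pool_spec()].
#' @return named numeric vector of nanograms per species in one reaction.
#' @export
per_reaction_ng <- function(pool) {
  stopifnot(inherits(pool, "pool_spec"))
  pool$reaction_ng * pool$masses / sum(pool$masses)
}

#' Mammalian/avian class of the thirteen study species
#'
#' @return named character vector, species -> `"mammal"` or `"avian"`.
#' @export
meat_species_classes <- function() {
  c(pig = "mammal", horse = "mammal", cattle = "mammal", sheep = "mammal",
    rabbit = "mammal", human = "mammal", rat = "mammal",
    chicken = "avian", turkey = "avian", pheasant = "avian",
    duck = "avian", goose = "avian", pigeon = "avian")
}

#' The study's DNA pool designs
#'
#' Six pools: (a) seven mammalian species at 100 ng each; (b) six avian
#' species at 100 ng each; (c1, c2) replicate pools of all 13 species at
#' 100 ng each; (d) the mammalian pool with pig and horse at 1/10 (10 ng);
#' (e) the mammalian pool with pig and horse at 1/50 (2 ng). Every PCR draws
#' 20 ng of pooled DNA.
#'
#' @return named list of [pool_spec()] objects.
#' @export
meat_pools <- function() {
  cls <- meat_species_classes()
  mam <- names(cls)[cls == "mammal"]
  avi <- names(cls)[cls == "avian"]
  eq <- function(sp) setNames(rep(100, length(sp)), sp)
  dil <- function(ng) {
    m <- eq(mam)
    m[c("pig", "horse")] <- ng
    m
  }
  list(a = pool_spec("a", eq(mam)),
       b = pool_spec("b", eq(avi)),
       c1 = pool_spec("c1", eq(c(mam, avi))),
       c2 = pool_spec("c2", eq(c(mam, avi))),
       d = pool_spec("d", dil(10)),
       e = pool_spec("e", dil(2)))
}

#' Read / write a pool spec as YAML or JSON
#'
#' Fields: `name`, `masses` (species -> ng), `reaction_ng`.
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @param pool a [pool_spec()].
#' @export
read_pool_spec <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  pool_spec(x$name, unlist(x$masses),
            if (is.null(x$reaction_ng)) 20 else x$reaction_ng)
}

#' @rdname read_pool_spec
#' @export
write_pool_spec <- function(pool, path) {
  x <- list(name = pool$name, masses = as.list(pool$masses),
            reaction_ng = pool$reaction_ng)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
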