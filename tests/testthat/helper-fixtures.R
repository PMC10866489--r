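# Shared fixtures and independent oracles. The oracles are deliberately
# naive (loops, exhaustive enumeration, direct ECDF evaluation) and never
# call the implementation paths they check.

VOCAB <- elementVocabulary()

# 10 characters: 6 requiring the frontal (skull), 3 requiring the femur
# (hindlimb), 1 requiring frontal+femur. Limb-free applicable set = 6.
fixture_map10 <- function() {
  characterRegionMap(c(rep(list("frontal"), 6), rep(list("femur"), 3),
                       list(c("frontal", "femur"))),
                     vocabulary = VOCAB)
}

random_map <- function(n_char, max_req = 3L) {
  elements <- replicate(n_char, {
    k <- sample.int(max_req, 1, prob = c(0.7, 0.2, 0.1)[seq_len(max_req)])
    sample(VOCAB$element, k)
  }, simplify = FALSE)
  characterRegionMap(elements, vocabulary = VOCAB)
}

random_record <- function(id = "sp", p = 0.4, limbless = FALSE) {
  pool <- VOCAB$element
  if (limbless) {
    pool <- VOCAB$element[!VOCAB$partition %in% limbPartitions()]
  }
  preservationRecord(id, pool[stats::runif(length(pool)) < p],
                     limbless = limbless,
                     n_specimens = sample.int(3, 1), vocabulary = VOCAB)
}

# brute-force CCM2: test every character's required set independently
oracle_ccm2 <- function(map, record) {
  part <- stats::setNames(VOCAB$partition, VOCAB$element)
  scorable <- 0L
  applicable <- 0L
  for (req in map$characters$elements) {
    if (record$limbless && any(part[req] %in% limbPartitions())) next
    applicable <- applicable + 1L
    if (all(req %in% record$elements)) scorable <- scorable + 1L
  }
  list(scorable = scorable, applicable = applicable,
       ccm2 = 100 * scorable / applicable)
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of which ranks
# go to x (tie-free samples only)
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# KS D by direct ECDF evaluation at every observed point
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# occurrence-table row in the schema loadAndVet() expects
occ_row <- function(name, rank = "species", extant = FALSE,
                    group = "squamate", landmass = "Asia",
                    formation = "Djadokhta", environment = "aeolian",
                    lager = "none", max_ma = 75, min_ma = 71,
                    n_spec = 1, n_loc = 1, limbless = FALSE) {
  data.frame(accepted_name = name, accepted_rank = rank, is_extant = extant,
             taxon_group = group, landmass = landmass, formation = formation,
             environment = environment, lagerstatte_class = lager,
             max_ma = max_ma, min_ma = min_ma, n_specimens = n_spec,
             n_localities = n_loc, limbless = limbless,
             stringsAsFactors = FALSE)
}

# minimal single-unit simulation config over an arbitrary map
tiny_sim_config <- function(seed, map, q = 0.5, lambda = 1, n = 20,
                            units = NULL, allocation = NULL,
                            limbless_fraction = 0) {
  if (is.null(units)) {
    units <- data.frame(unit = "U1", landmass = "Asia",
                        environment = "fluvial", lagerstatte_class = "none",
                        q = q, lambda = lambda, max_ma = 80, min_ma = 70,
                        stringsAsFactors = FALSE)
  }
  if (is.null(allocation)) {
    allocation <- data.frame(taxon_group = "squamate", unit = units$unit[1],
                             n = n, stringsAsFactors = FALSE)
  }
  fragility <- stats::setNames(rep(1, length(ccmPartitions())),
                               ccmPartitions())
  limbless <- c(squamate = limbless_fraction, non_avian_theropod = 0,
                mesozoic_bird = 0)
  simulationConfig(seed, units, allocation, fragility, limbless, map)
}

# two-unit config used by the parameter-recovery checks: q = 0.9 vs 0.3,
# 50 species each, lambda = 1
two_unit_config <- function(seed, map = squamateCharacterMap()) {
  units <- data.frame(
    unit = c("HighQ", "LowQ"), landmass = c("Asia", "Asia"),
    environment = c("aeolian", "fluvial"),
    lagerstatte_class = c("none", "none"),
    q = c(0.9, 0.3), lambda = c(1, 1),
    max_ma = c(75, 75), min_ma = c(70, 70), stringsAsFactors = FALSE)
  allocation <- data.frame(taxon_group = "squamate",
                           unit = c("HighQ", "LowQ"), n = c(50, 50),
                           stringsAsFactors = FALSE)
  fragility <- c(skull = 0.5, mandible = 0.65, axial = 0.7,
                 pectoral_girdle = 0.5, forelimb = 0.45,
                 pelvic_girdle = 0.5, hindlimb = 0.45, integument = 0.1)
  simulationConfig(seed, units, allocation, fragility,
                   c(squamate = 0), map)
}

nexus_fixture_5x10 <- function(path) {
  # 7 '?' cells by hand count: 2 + 1 + 3 + 0 + 1
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=5 NCHAR=10;",
    "FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;",
    "MATRIX",
    "taxon_a 01201??120",
    "taxon_b 0120110?20",
    "taxon_c ???2110120",
    "taxon_d 01-2110120",
    "taxon_e 0120?10120",
    ";",
    "END;"), path)
  path
}
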