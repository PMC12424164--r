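# Shared fixtures and the independent LP oracle.

# Independent brute-force oracle for max c'x s.t. A x = b, l <= x <= u:
# enumerate candidate vertices by fixing (n - rank) coordinates at bounds
# and solving the square remainder. Exponential; only for tiny systems.
oracle_lp <- function(A, b, l, u, cc) {
  A <- as.matrix(A)
  n <- ncol(A)
  rk <- qr(A)$rank
  best <- -Inf
  feas <- FALSE
  register <- function(x) {
    if (max(abs(A %*% x - b)) > 1e-7) return()
    if (all(x >= l - 1e-8 & x <= u + 1e-8)) {
      feas <<- TRUE
      best <<- max(best, sum(cc * x))
    }
  }
  free_ct <- n - rk
  if (free_ct == 0) {
    x <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(x)) register(x)
  } else {
    combs <- utils::combn(n, free_ct)
    for (k in seq_len(ncol(combs))) {
      fx <- combs[, k]
      for (mask in 0:(2^free_ct - 1)) {
        vals <- ifelse(bitwAnd(mask, 2^(seq_len(free_ct) - 1)) > 0,
                       u[fx], l[fx])
        rest <- setdiff(seq_len(n), fx)
        sol <- tryCatch(
          qr.solve(A[, rest, drop = FALSE],
                   b - A[, fx, drop = FALSE] %*% vals),
          error = function(e) NULL)
        if (is.null(sol)) next
        x <- numeric(n)
        x[fx] <- vals
        x[rest] <- sol
        register(x)
      }
    }
  }
  list(feasible = feas, value = if (feas) best else NA_real_)
}

# 3-reaction linear chain A_in -> A -> B -> B_out with bounds [0, 10]
chain_model <- function(ub = 10) {
  model_from_equations(
    id = "chain",
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(
      id = c("a_c", "b_c", "a_e", "b_e"),
      formula = c("C", "C", "C", "C"), charge = 0L,
      compartment = c("c", "c", "e", "e")),
    reactions = data.frame(
      id = c("EX_a_e", "T_a", "R1", "T_b", "EX_b_e"),
      equation = c("a_e ->", "a_e -> a_c", "a_c -> b_c", "b_c -> b_e",
                   "b_e ->"),
      lower_bound = c(-ub, 0, 0, 0, 0),
      upper_bound = c(0, ub, ub, ub, ub)),
    objective_id = "EX_b_e")
}

# 1-D box polytope: single free flux through two reactions, both in [0, w]
box_model <- function(w = 2) {
  model_from_equations(
    id = "box",
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(id = c("a_c", "a_e"), formula = c("C", "C"),
                             charge = 0L, compartment = c("c", "e")),
    reactions = data.frame(
      id = c("EX_a_e", "T_in", "SINK"),
      equation = c("a_e ->", "a_e -> a_c", "a_c ->"),
      lower_bound = c(-w, 0, 0), upper_bound = c(0, w, w)),
    objective_id = "SINK")
}

# tiny two-species fixture: producer secretes "m", consumer eats it
mini_producer <- function() {
  model_from_equations(
    id = "producer",
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(
      id = c("s_e", "s_c", "m_c", "m_e", "biomass_c"),
      formula = c("C2", "C2", "C2", "C2", "C2"), charge = 0L,
      compartment = c("e", "c", "c", "e", "c")),
    reactions = data.frame(
      id = c("EX_s_e", "T_s", "CONV", "T_m", "EX_m_e", "Biomass",
             "DM_biomass"),
      equation = c("s_e ->", "s_e -> s_c", "s_c -> m_c", "m_c -> m_e",
                   "m_e ->", "s_c -> biomass_c", "biomass_c ->"),
      lower_bound = c(-5, 0, 0, 0, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000, 1000, 1000, 1000)),
    objective_id = "Biomass")
}

mini_consumer <- function() {
  model_from_equations(
    id = "consumer",
    compartments = c(c = "cytosol", e = "extracellular"),
    metabolites = data.frame(
      id = c("m_e", "m_c", "p_c", "p_e", "biomass_c"),
      formula = c("C2", "C2", "C2", "C2", "C2"), charge = 0L,
      compartment = c("e", "c", "c", "e", "c")),
    reactions = data.frame(
      id = c("EX_m_e", "T_m", "CONV", "T_p", "EX_p_e", "Biomass",
             "DM_biomass"),
      equation = c("m_e ->", "m_e -> m_c", "m_c -> p_c", "p_c -> p_e",
                   "p_e ->", "m_c -> biomass_c", "biomass_c ->"),
      lower_bound = c(0, 0, 0, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000, 1000)),
    objective_id = "Biomass")
}

paper_condition <- function(fractions = c(aw = 0.5, an = 0.3, ck = 0.2),
                            mu = 0.02, X = 0.32,
                            co = c(-3.5, -1)) {
  community_condition(mu, X, fractions, list(EX_co_e = co))
}
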