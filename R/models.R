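#' @useDynLib mcaspolarity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef uniroot rnorm runif setNames
NULL

.kernel_ids <- c(none = 0L, minimal = 1L, indirect = 2L,
                 mechanistic = 3L, mechanistic_nfb = 4L)

new_mcas_model <- function(name, kernel, species, params, groups,
                           activator, substrates, one_x, derived = list()) {
  structure(list(
    name = name,
    kernel = kernel,
    species = species,       # data.frame: name, compartment, D
    params = params,         # named list, kernel ordering handled separately
    groups = groups,         # list of named weight vectors, one per group
    activator = activator,   # species whose peaks are scored
    substrates = substrates, # cytoplasmic species with meaningful basal levels
    one_x = one_x,           # uniform starting concentrations defining "1x"
    derived = derived
  ), class = "mcas_model")
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("parameter '%s' must be a single positive number", what),
         call. = FALSE)
  invisible(x)
}

#' Minimalistic MCAS polarity model
#'
#' Two-species mass-conserved activator-substrate model of a single
#' Rho-GTPase: a slow membrane-bound activator `u` (GTP-form) and a fast
#' cytosolic substrate `v` (GDP-form). Substrate is converted to activator
#' autocatalytically (rate `a u^2 v`, the implicit positive feedback) and
#' activator decays back to substrate in a first-order process (rate `b u`).
#' The total amount `u + v` is conserved; there is no synthesis or
#' degradation. All quantities are dimensionless.
#'
#' @param a Autocatalytic activation rate coefficient (default 1).
#' @param b First-order inactivation rate (default 1).
#' @param Dm Activator (membrane) diffusivity (default 0.01).
#' @param Dc Substrate (cytosol) diffusivity (default 1).
#' @return An object of class `mcas_model`.
#' @examples
#' m <- minimal_model()
#' reaction_rates(m, c(u = 2, v = 2))  # du = +6, dv = -6
#' @export
minimal_model <- function(a = 1, b = 1, Dm = 0.01, Dc = 1) {
  check_positive(a, "a"); check_positive(b, "b")
  check_positive(Dm, "Dm"); check_positive(Dc, "Dc")
  if (Dm >= Dc)
    stop("the membrane activator must diffuse slower than the substrate")
  new_mcas_model(
    name = "minimal",
    kernel = .kernel_ids[["minimal"]],
    species = data.frame(
      name = c("u", "v"),
      compartment = c("membrane", "cytoplasm"),
      D = c(Dm, Dc),
      stringsAsFactors = FALSE),
    params = list(a = a, b = b),
    groups = list(total = c(u = 1, v = 1)),
    activator = "u",
    substrates = "v",
    one_x = c(u = 0, v = 2))
}

#' Indirect-substrate MCAS model
#'
#' Extension of [minimal_model()] with a third species, the indirect
#' substrate `vi`: besides the direct conversion of activator back to
#' substrate, `u` is converted to the mobile intermediate `vi` (first order,
#' rate `c u`), which in turn converts to the substrate `v` (rate `d vi`).
#' The delayed, diffusible return path is what enables equalization of
#' unequal activator peaks. Total `u + v + vi` is conserved.
#'
#' @param a,b As in [minimal_model()].
#' @param c_ Activator-to-indirect-substrate rate (default 0.01).
#' @param d Indirect-substrate-to-substrate rate (default 1).
#' @param Dm,Dc Activator / substrate diffusivities.
#' @param Dvi Indirect-substrate diffusivity (default 1); the key control
#'   parameter of the outcome phase diagram.
#' @return An object of class `mcas_model`.
#' @export
indirect_model <- function(a = 1, b = 1, c_ = 0.01, d = 1,
                           Dm = 0.01, Dc = 1, Dvi = 1) {
  check_positive(a, "a"); check_positive(b, "b")
  check_positive(c_, "c"); check_positive(d, "d")
  check_positive(Dm, "Dm"); check_positive(Dc, "Dc"); check_positive(Dvi, "Dvi")
  if (Dm >= Dc)
    stop("the membrane activator must diffuse slower than the substrate")
  new_mcas_model(
    name = "indirect",
    kernel = .kernel_ids[["indirect"]],
    species = data.frame(
      name = c("u", "v", "vi"),
      compartment = c("membrane", "cytoplasm", "cytoplasm"),
      D = c(Dm, Dc, Dvi),
      stringsAsFactors = FALSE),
    params = list(a = a, b = b, c = c_, d = d),
    groups = list(total = c(u = 1, v = 1, vi = 1)),
    activator = "u",
    substrates = c("v", "vi"),
    one_x = c(u = 0, v = 2, vi = 0))
}

.mech_defaults <- function(negative_feedback) {
  p <- list(k1a = 10, k1b = 10, k2a = 0.16, k2b = 1.75, k3 = 0.35,
            k4a = 10, k4b = 10, k5a = 36, k5b = 0.65, k7 = 10,
            eta = 0.01, Dm = 0.0025, Dc = 10)
  if (negative_feedback) {
    p$k2b <- 0.35
    p <- c(p, list(k8max = 0.0063, k8n = 6, k8h = 10,
                   k9max = 0.0044, k9n = 6, k9h = 0.003))
  }
  p
}

#' Mechanistic yeast polarity circuit model
#'
#' Mass-action model of the budding-yeast Cdc42 polarity circuit. Cdc42
#' cycles between active GTP-bound (`Cdc42T`), membrane GDP-bound
#' (`Cdc42Dm`) and cytosolic GDP-bound (`Cdc42Dc`) forms; the scaffold-GEF
#' complex ("BemGEF", representing PAK-Bem1-Cdc24) exchanges between
#' cytosol (`BemGEFc`) and membrane (`BemGEFm`) and binds `Cdc42T` to form
#' the membrane complex `BemGEF42`, which activates neighbouring Cdc42
#' (positive feedback). With `negative_feedback = TRUE` the GEF is
#' phosphorylated (species `BemGEFm_p`, `BemGEFc_p`, `BemGEF42_p`) by
#' Cdc42-bound complexes in an ultrasensitive (Hill) manner and
#' dephosphorylated in the cytoplasm; phosphorylated GEF still binds
#' membranes and `Cdc42T` but has no GEF activity.
#'
#' Membrane/cytosol exchange is weighted by the membrane-to-cytoplasm volume
#' ratio `eta`; conserved totals therefore weight cytosolic species by
#' `1/eta`. Units: concentrations in uM, time in s, space in um.
#'
#' The Hill arguments of the phosphorylation (`k8`) and dephosphorylation
#' (`k9`) rates are configurable: `k8_arg` is `"BemGEF42t"` (default, the
#' total Cdc42-bound complex) or `"BemGEFmt"`; `k9_arg` is `"BemGEFc_p"`
#' (default, cytosolic phosphorylated GEF) or `"BemGEFm_p"`.
#'
#' @param negative_feedback Include the GEF-phosphorylation negative
#'   feedback loop (9 species instead of 6)?
#' @param params Named list of parameter overrides.
#' @param k8_arg,k9_arg Hill-argument choices, see Details.
#' @return An object of class `mcas_model`.
#' @export
mechanistic_model <- function(negative_feedback = FALSE, params = list(),
                              k8_arg = c("BemGEF42t", "BemGEFmt"),
                              k9_arg = c("BemGEFc_p", "BemGEFm_p")) {
  k8_arg <- match.arg(k8_arg)
  k9_arg <- match.arg(k9_arg)
  p <- .mech_defaults(negative_feedback)
  unknown <- setdiff(names(params), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(params)] <- params
  if (p$eta <= 0 || p$eta > 1) stop("eta must lie in (0, 1]")
  rates <- setdiff(names(p), c("eta", "Dm", "Dc"))
  for (nm in rates)
    if (p[[nm]] < 0) stop(sprintf("rate constant '%s' must be >= 0", nm))
  mem <- c("Cdc42T", "Cdc42Dm", "BemGEF42", "BemGEFm")
  cyt <- c("Cdc42Dc", "BemGEFc")
  if (negative_feedback) {
    mem <- c(mem, "BemGEFm_p", "BemGEF42_p")
    cyt <- c(cyt, "BemGEFc_p")
  }
  sp_names <- if (negative_feedback)
    c("Cdc42T", "Cdc42Dm", "BemGEF42", "BemGEFm", "Cdc42Dc", "BemGEFc",
      "BemGEFm_p", "BemGEFc_p", "BemGEF42_p")
  else
    c("Cdc42T", "Cdc42Dm", "BemGEF42", "BemGEFm", "Cdc42Dc", "BemGEFc")
  species <- data.frame(
    name = sp_names,
    compartment = ifelse(sp_names %in% cyt, "cytoplasm", "membrane"),
    D = ifelse(sp_names %in% cyt, p$Dc, p$Dm),
    stringsAsFactors = FALSE)
  w <- function(nms) setNames(ifelse(nms %in% cyt, 1 / p$eta, 1), nms)
  groups <- if (negative_feedback) list(
    Cdc42 = w(c("Cdc42T", "Cdc42Dm", "BemGEF42", "BemGEF42_p", "Cdc42Dc")),
    BemGEF = w(c("BemGEFm", "BemGEF42", "BemGEFc",
                 "BemGEFm_p", "BemGEF42_p", "BemGEFc_p")))
  else list(
    Cdc42 = w(c("Cdc42T", "Cdc42Dm", "BemGEF42", "Cdc42Dc")),
    BemGEF = w(c("BemGEFm", "BemGEF42", "BemGEFc")))
  # "1x" uniform starting cytosolic concentrations (uM); not printed for this
  # model, adopted defaults exposed here and overridable in assays.
  one_x <- setNames(numeric(length(sp_names)), sp_names)
  one_x["Cdc42Dc"] <- 5.0
  one_x["BemGEFc"] <- 0.017
  p$k8_arg <- if (negative_feedback) k8_arg else NULL
  p$k9_arg <- if (negative_feedback) k9_arg else NULL
  new_mcas_model(
    name = if (negative_feedback) "mechanistic_nfb" else "mechanistic",
    kernel = .kernel_ids[[if (negative_feedback) "mechanistic_nfb"
                          else "mechanistic"]],
    species = species,
    params = p,
    groups = groups,
    activator = "Cdc42T",
    substrates = c("Cdc42Dc", "BemGEFc"),
    one_x = one_x,
    derived = list(
      BemGEFmt = c("BemGEFm", "BemGEFm_p"),
      BemGEFct = c("BemGEFc", "BemGEFc_p"),
      BemGEF42t = c("BemGEF42", "BemGEF42_p")))
}

# parameter vector in the ordering the C++ kernels expect
kernel_params <- function(model) {
  p <- model$params
  if (model$kernel == 0L) return(numeric(0))
  switch(model$name,
    minimal = c(p$a, p$b),
    indirect = c(p$a, p$b, p$c, p$d),
    mechanistic = c(p$k1a, p$k1b, p$k2a, p$k2b, p$k3, p$k4a, p$k4b,
                    p$k5a, p$k5b, p$k7, p$eta),
    mechanistic_nfb = c(p$k1a, p$k1b, p$k2a, p$k2b, p$k3, p$k4a, p$k4b,
                        p$k5a, p$k5b, p$k7, p$eta,
                        p$k8max, p$k8n, p$k8h, p$k9max, p$k9n, p$k9h,
                        if (identical(p$k8_arg, "BemGEFmt")) 1 else 0,
                        if (identical(p$k9_arg, "BemGEFm_p")) 1 else 0),
    stop("no kernel parameters for model ", model$name))
}

n_species <- function(model) nrow(model$species)

#' Evaluate reaction rates of a model
#'
#' Applies the model's reaction kinetics pointwise (no diffusion). Mass
#' conservation holds exactly: for every conservation group the weighted sum
#' of rates is zero at any state.
#'
#' @param model An `mcas_model`.
#' @param state Named numeric vector of concentrations, or a matrix with one
#'   column per species (columns in `model$species$name` order).
#' @return Rates in the same shape as `state`.
#' @export
reaction_rates <- function(model, state) {
  nm <- model$species$name
  if (is.matrix(state)) {
    stopifnot(ncol(state) == length(nm))
    r <- react_rates_cpp(state, model$kernel, kernel_params(model))
    colnames(r) <- nm
    r
  } else {
    state <- state[nm]
    if (anyNA(state)) stop("state must name every species of the model")
    r <- react_rates_cpp(matrix(state, nrow = 1), model$kernel,
                         kernel_params(model))
    setNames(drop(r), nm)
  }
}

#' Homogeneous steady states of a model
#'
#' Finds spatially uniform states with vanishing reaction rates under the
#' requested conserved totals. For the minimal model the non-trivial roots
#' satisfy `u * v = b / a` with `u + v = total` (closed form, plus the
#' trivial all-substrate state); the indirect model is likewise closed-form.
#' Mechanistic models are solved numerically (pointwise ODE relaxation
#' followed by Newton polishing).
#'
#' @param model An `mcas_model`.
#' @param totals Named vector of conserved totals, one per conservation
#'   group (weighted concentrations; cytosolic species count `1/eta`-fold in
#'   the mechanistic models). A single unnamed number is accepted for
#'   single-group models.
#' @return A list of homogeneous states (named concentration vectors); the
#'   first element is the trivial/least-activated root where present.
#' @export
homogeneous_steady_state <- function(model, totals) {
  gn <- names(model$groups)
  if (is.null(names(totals)) && length(totals) == length(gn))
    names(totals) <- gn
  if (!all(gn %in% names(totals)))
    stop("totals must be named for groups: ", paste(gn, collapse = ", "))
  if (any(totals < 0)) stop("totals must be >= 0")
  nm <- model$species$name
  out <- switch(model$name,
    minimal = {
      T <- totals[["total"]]
      a <- model$params$a; b <- model$params$b
      roots <- list(c(u = 0, v = T))
      disc <- T^2 - 4 * b / a
      if (disc >= 0) {
        for (u in sort(unique((T + c(-1, 1) * sqrt(disc)) / 2)))
          if (u > 0) roots[[length(roots) + 1L]] <- c(u = u, v = T - u)
      }
      roots
    },
    indirect = {
      T <- totals[["total"]]
      a <- model$params$a; b <- model$params$b
      cc <- model$params$c; d <- model$params$d
      roots <- list(c(u = 0, v = T, vi = 0))
      # u*v = (b+c)/a, vi = (c/d) u, u + v + vi = T
      A <- 1 + cc / d; B <- -T; C <- (b + cc) / a
      disc <- B^2 - 4 * A * C
      if (disc >= 0) {
        for (u in sort(unique((-B + c(-1, 1) * sqrt(disc)) / (2 * A))))
          if (u > 0)
            roots[[length(roots) + 1L]] <-
              c(u = u, v = (b + cc) / (a * u), vi = cc * u / d)
      }
      roots
    },
    {
      # mechanistic models: relax the pointwise ODE from an all-cytosolic
      # state, then Newton-polish the algebraic system
      eta <- model$params$eta
      x0 <- setNames(numeric(length(nm)), nm)
      x0["Cdc42Dc"] <- totals[["Cdc42"]] * eta
      x0["BemGEFc"] <- totals[["BemGEF"]] * eta
      g <- mcas_grid(n = 1, length = 1)
      st <- mcas_state(matrix(x0, nrow = 1, dimnames = list(NULL, nm)))
      res <- imex_integrate_cpp(st$fields, 1L, 1L, 1, 1, 1L, integer(),
                                model$species$D, model$kernel,
                                kernel_params(model),
                                0, 5e4, numeric(), 1e-6, 1e-3, 1e-12, 10,
                                1e-12, 1e9, 1e-7)
      x <- setNames(drop(res$state), nm)
      x <- polish_hss(model, x, totals)
      list(x)
    })
  lapply(out, function(x) structure(x, class = "mcas_hss"))
}

# Newton iteration on [reaction rates; conserved-total residuals], solved in
# the least-squares sense (the rate equations are rank-deficient by one per
# conservation group).
polish_hss <- function(model, x, totals, iter = 50, tol = 1e-13) {
  nm <- model$species$name
  Gw <- model$groups
  fn <- function(x) {
    r <- reaction_rates(model, setNames(x, nm))
    cons <- vapply(names(Gw), function(g)
      sum(Gw[[g]] * x[match(names(Gw[[g]]), nm)]) - totals[[g]], numeric(1))
    c(r, cons)
  }
  for (i in seq_len(iter)) {
    f0 <- fn(x)
    if (max(abs(f0)) < tol * max(1, max(abs(x)))) break
    J <- matrix(0, length(f0), length(x))
    h <- pmax(abs(x), 1e-6) * 1e-7
    for (j in seq_along(x)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- (fn(xp) - f0) / h[j]
    }
    dx <- tryCatch(qr.solve(J, -f0), error = function(e) NULL)
    if (is.null(dx)) break
    step <- 1
    repeat {
      xn <- x + step * dx
      if (all(xn >= 0) || step < 1e-4) break
      step <- step / 2
    }
    x <- pmax(x + step * dx, 0)
  }
  setNames(x, nm)
}

#' Linear growth rate of a perturbation about a homogeneous steady state
#'
#' Linearizes the reaction-diffusion system about a homogeneous steady state
#' and returns the largest real part among the eigenvalues of
#' `J - q^2 diag(D)`, where `J` is the reaction Jacobian and `q` the
#' wavenumber of the perturbation. A positive value at some `q` signals a
#' Turing-type instability of the uniform state. At `q = 0` each
#' conservation group contributes one exactly-zero eigenvalue.
#'
#' @param model An `mcas_model`.
#' @param hss Homogeneous state (named concentrations); must be steady.
#' @param q Wavenumber (scalar or vector).
#' @return Numeric vector of leading growth rates, one per `q`, with the
#'   full eigenvalue sets in attribute `"eigenvalues"`.
#' @export
linear_growth_rate <- function(model, hss, q) {
  nm <- model$species$name
  x <- unclass(hss)[nm]
  r <- reaction_rates(model, x)
  if (max(abs(r)) > 1e-8 * max(1, max(abs(x))))
    stop("'hss' is not a steady state of the reaction kinetics")
  J <- reaction_jacobian(model, x)
  D <- model$species$D
  ev <- lapply(q, function(qi) eigen(J - qi^2 * diag(D, length(D)),
                                     only.values = TRUE)$values)
  out <- vapply(ev, function(e) max(Re(e)), numeric(1))
  attr(out, "eigenvalues") <- ev
  out
}

# central-difference reaction Jacobian at a uniform state
reaction_jacobian <- function(model, x) {
  nm <- model$species$name
  x <- x[nm]
  n <- length(x)
  J <- matrix(0, n, n, dimnames = list(nm, nm))
  h <- pmax(abs(x), 1e-4) * 1e-6
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h[j]; xm[j] <- xm[j] - h[j]
    J[, j] <- (reaction_rates(model, xp) - reaction_rates(model, xm)) /
      (2 * h[j])
  }
  J
}

#' Strip the reaction term from a model
#'
#' Returns a copy of the model whose reaction rates are identically zero,
#' leaving pure multi-species diffusion. Useful for validating the
#' diffusion operator against closed-form heat kernels.
#'
#' @param model An `mcas_model`.
#' @return The model with a zero reaction kernel.
#' @export
diffusion_only <- function(model) {
  model$kernel <- .kernel_ids[["none"]]
  model$name <- paste0(model$name, "_diffusion_only")
  model
}

#' Conserved "1x" totals of a model
#'
#' Weighted conserved totals corresponding to the model's reference ("1x")
#' uniform starting condition (minimal/indirect: uniform substrate `v = 2`;
#' mechanistic: cytosolic Cdc42 5.0 uM and BemGEF 0.017 uM).
#'
#' @param model An `mcas_model`.
#' @return Named numeric vector, one total per conservation group.
#' @export
model_1x_totals <- function(model) {
  nm <- model$species$name
  vapply(model$groups, function(w)
    sum(w * model$one_x[match(names(w), nm)]), numeric(1))
}

#' @export
print.mcas_model <- function(x, ...) {
  cat("MCAS model:", x$name, "\n")
  cat("  species:",
      paste(sprintf("%s (%s, D=%g)", x$species$name, x$species$compartment,
                    x$species$D), collapse = ", "), "\n")
  cat("  conservation groups:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}
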