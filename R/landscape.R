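#' Symmetric fitness landscapes on the class coordinate x
#'
#' Constructs a fitness landscape for the quasispecies models.  A symmetric
#' landscape assigns fitness by Hamming class only, through a function of the
#' mean spin `x = 1 - 2 l / L` with `x` in `[-1, 1]`; `l = 0` (all reference
#' alleles, `x = 1`) is the reference class.  The wild-type map `f` and the
#' mutator-type map `g` may differ; by default `g = f`.
#'
#' Families:
#' \describe{
#'   \item{`linear`}{`f(x) = k x`.  Parameter `k`.}
#'   \item{`quadratic`}{`f(x) = c x^2 / 2`.  Parameter `c`.}
#'   \item{`single_peak`}{`f(1) = J`, `f(x) = 0` otherwise (peak exactly at
#'     class `l = 0`).  Parameter `J > 0`.}
#'   \item{`tabulated`}{arbitrary symmetric values on the class grid of a
#'     fixed `L`; parameters `values` (length `L + 1`, class order
#'     `l = 0..L`) and `L`.}
#'   \item{`composite_d`}{additive d-dimensional landscape; parameter
#'     `parts`, a list of parts as used by [multidim_potential()].}
#'   \item{`lognormal_random`}{log-normal Wrightian fitness values on full
#'     sequence space (Eigen-model side); parameters `meanlog`, `sdlog`,
#'     `seed`.  Evaluation is through [lognormal_wrightians()] /
#'     [lognormal_effective_peak()]; the `f`/`g` maps of this object give the
#'     background fitness 1.}
#' }
#'
#' For the Crow-Kimura solvers the values are Malthusian growth rates; the
#' Eigen-model functions interpret values as Wrightian (multiplicative)
#' fitnesses.  Conversion between the two conventions happens only in
#' [ck_eigen_map()].
#'
#' @param family One of `"linear"`, `"quadratic"`, `"single_peak"`,
#'   `"tabulated"`, `"composite_d"`, `"lognormal_random"`.
#' @param ... Family parameters (see Details).  For distinct mutator-type
#'   fitness supply `g_values` (tabulated) or `g_fun` (a function of `x`).
#' @return Object of class `"fitness_landscape"`: list with `kind`, callable
#'   maps `f` and `g`, and `params`.
#' @examples
#' make_landscape("linear", k = 1)$f(0.5)        # 0.5
#' make_landscape("quadratic", c = 3)$f(1)       # 1.5
#' sp <- make_landscape("single_peak", J = 1.05)
#' sp$f(1); sp$f(1 - 2 / 100)                    # 1.05, 0
#' @export
make_landscape <- function(family, ...) {
  params <- list(...)
  kind <- match.arg(family, c("linear", "quadratic", "single_peak",
                              "tabulated", "composite_d", "lognormal_random"))
  f <- switch(kind,
    linear = {
      if (is.null(params$k)) stop("'linear' needs parameter 'k'")
      k <- params$k
      function(x) k * x
    },
    quadratic = {
      if (is.null(params$c)) stop("'quadratic' needs parameter 'c'")
      cc <- params$c
      function(x) cc * x^2 / 2
    },
    single_peak = {
      if (is.null(params$J)) stop("'single_peak' needs parameter 'J'")
      if (params$J <= 0) stop("single-peak height 'J' must be positive")
      J <- params$J
      function(x) ifelse(x == 1, J, 0)
    },
    tabulated = {
      v <- params$values; L <- params$L
      if (is.null(v) || is.null(L)) stop("'tabulated' needs 'values' and 'L'")
      if (length(v) != L + 1L || any(!is.finite(v)))
        stop("'values' must be finite and of length L + 1")
      function(x) {
        l <- round((1 - x) * L / 2)
        if (any(abs((1 - x) * L / 2 - l) > 1e-8))
          stop("tabulated landscape evaluated off the class grid")
        v[l + 1L]
      }
    },
    composite_d = {
      parts <- params$parts
      if (is.null(parts)) stop("'composite_d' needs 'parts'")
      y <- vapply(parts, function(p) p$y, numeric(1))
      if (any(y <= 0)) stop("part weights y_i must be positive")
      if (abs(sum(y) - 1) > 1e-10) stop("part weights y_i must sum to 1")
      function(x) {
        if (length(x) != length(parts))
          stop("composite landscape needs one coordinate per part")
        sum(vapply(seq_along(parts),
                   function(i) parts[[i]]$f(x[i]), numeric(1)))
      }
    },
    lognormal_random = {
      if (is.null(params$sdlog)) stop("'lognormal_random' needs 'sdlog'")
      if (params$sdlog <= 0) stop("'sdlog' must be positive")
      function(x) rep(1, length(x))  # background Wrightian fitness
    })
  g <- if (!is.null(params$g_fun)) params$g_fun
       else if (!is.null(params$g_values) && kind == "tabulated") {
         gv <- params$g_values; L <- params$L
         if (length(gv) != L + 1L) stop("'g_values' must have length L + 1")
         function(x) {
           l <- round((1 - x) * L / 2)
           gv[l + 1L]
         }
       } else f
  structure(list(kind = kind, f = f, g = g, params = params),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("fitness landscape: %s\n", x$kind))
  pp <- x$params[!vapply(x$params, is.function, logical(1))]
  pp <- pp[!vapply(pp, is.list, logical(1))]
  if (length(pp))
    cat("  ", paste(names(pp), unlist(pp), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a landscape on the Hamming-class grid
#'
#' Tabulates `f` and `g` at `x_l = 1 - 2 l / L` for `l = 0..L`.
#'
#' @param landscape A [make_landscape()] object.
#' @param L Genome length defining the grid.
#' @return `data.frame` with columns `l`, `x`, `f`, `g`.
#' @export
landscape_grid <- function(landscape, L) {
  l <- 0:L
  x <- 1 - 2 * l / L
  data.frame(l = l, x = x, f = landscape$f(x), g = landscape$g(x))
}

#' Seeded log-normal Wrightian fitness values
#'
#' Draws one Wrightian (multiplicative) fitness value per sequence of a
#' binary genome of length `L` from a log-normal distribution with median 1,
#' `log r ~ N(meanlog, sdlog^2)`.  With `2^L` independent draws the largest
#' value concentrates, to leading order in extreme-value theory, at
#' `A_max = exp(meanlog + sdlog * sqrt(2 L log 2))`, which serves as the
#' height of the effective single-peak landscape while the bulk of sequence
#' space keeps fitness about 1.
#'
#' @param L Genome length; full enumeration requires `L <= 20`.
#' @param sdlog Standard deviation of `log` fitness, `> 0`.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param meanlog Mean of `log` fitness (default 0, i.e. median fitness 1).
#' @param enumerate If `TRUE` (default for `L <= 20`) return the full vector
#'   of `2^L` draws; otherwise only distribution summaries.
#' @return List with `A_max` (closed-form effective peak height),
#'   `max_draw` (empirical maximum; `NA` when not enumerating), `values`
#'   (the draws or `NULL`), and the inputs.
#' @examples
#' a <- lognormal_wrightians(10, sdlog = 1, seed = 1)
#' b <- lognormal_wrightians(10, sdlog = 1, seed = 1)
#' identical(a$values, b$values)  # TRUE
#' @export
lognormal_wrightians <- function(L, sdlog, seed, meanlog = 0,
                                 enumerate = L <= 20) {
  if (sdlog <= 0) stop("'sdlog' must be positive")
  if (enumerate && L > 20) stop("full enumeration limited to L <= 20")
  A_max <- exp(meanlog + sdlog * sqrt(2 * L * log(2)))
  values <- NULL; max_draw <- NA_real_
  if (enumerate) {
    values <- withr_seed(seed, stats::rlnorm(2^L, meanlog, sdlog))
    max_draw <- max(values)
  }
  list(L = L, meanlog = meanlog, sdlog = sdlog, seed = seed,
       A_max = A_max, max_draw = max_draw, values = values)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a flat model configuration
#'
#' Serialises a parameter set and a landscape to a flat `key: value` text
#' file (YAML subset) and restores them.  Function-valued landscapes are
#' rebuilt from their family `kind` and parameters; `tabulated` values are
#' stored inline.
#'
#' @param params A [mutator_params()] object.
#' @param landscape A [make_landscape()] object (primitive families only).
#' @param path File path.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns `list(params, landscape)`.
#' @export
write_model_config <- function(params, landscape, path) {
  stopifnot(inherits(params, "mutator_params"),
            inherits(landscape, "fitness_landscape"))
  if (landscape$kind == "composite_d")
    stop("composite landscapes are not serialisable to a flat config")
  num <- landscape$params[vapply(landscape$params, is.numeric, logical(1))]
  lines <- c(
    sprintf("L: %d", params$L),
    sprintf("mu1: %.17g", params$mu1),
    sprintf("mu2: %.17g", params$mu2),
    sprintf("alpha1: %.17g", params$alpha1),
    sprintf("alpha2: %.17g", params$alpha2),
    sprintf("landscape: %s", landscape$kind),
    vapply(names(num), function(nm)
      sprintf("%s: %s", nm, paste(sprintf("%.17g", num[[nm]]), collapse = " ")),
      character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  kv <- strsplit(readLines(path), ":\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1))
  get1 <- function(k) vals[match(k, keys)]
  num1 <- function(k) as.numeric(strsplit(trimws(get1(k)), "\\s+")[[1]])
  params <- mutator_params(L = as.integer(get1("L")),
                           mu1 = num1("mu1"), mu2 = num1("mu2"),
                           alpha1 = num1("alpha1"), alpha2 = num1("alpha2"))
  kind <- trimws(get1("landscape"))
  extra <- setdiff(keys, c("L", "mu1", "mu2", "alpha1", "alpha2", "landscape"))
  args <- stats::setNames(lapply(extra, num1), extra)
  landscape <- do.call(make_landscape, c(list(family = kind), args))
  list(params = params, landscape = landscape)
}
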