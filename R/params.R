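#' Plasma pharmacokinetic parameters
#'
#' Parameter set of the two-compartment plasma model. `k12` and `k21` are the
#' inter-compartment transfer constants (peripheral -> central and
#' central -> peripheral respectively), `ketot` the total body removal
#' constant, all in L/min; `V1` and `V2` are the central and peripheral
#' compartment volumes in L. The volumes are fixed, standard 70-kg values by
#' default; only the three rate constants are subject-specific.
#'
#' @param k12 Peripheral-to-central transfer constant \[L/min\].
#' @param k21 Central-to-peripheral transfer constant \[L/min\].
#' @param ketot Total body removal constant \[L/min\].
#' @param V1 Central compartment volume \[L\].
#' @param V2 Peripheral compartment volume \[L\].
#' @return An object of class `pk_params` (named list).
#' @examples
#' pk_params(k12 = 10, k21 = 9.11, ketot = 0.80)
#' @export
pk_params <- function(k12, k21, ketot, V1 = 11, V2 = 38) {
  p <- list(k12 = k12, k21 = k21, ketot = ketot, V1 = V1, V2 = V2)
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  need <- c("k12", "k21", "ketot", "V1", "V2")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("pk_params: missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (nm in need) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("pk_params: `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  for (nm in c("k12", "k21", "V1", "V2")) {
    if (p[[nm]] <= 0) {
      stop("pk_params: `", nm, "` must be positive", call. = FALSE)
    }
  }
  # ketot = 0 (no elimination) is allowed so mass balance is checkable
  if (p$ketot < 0) stop("pk_params: `ketot` must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>  k12 =", x$k12, " k21 =", x$k21, " ketot =", x$ketot,
      " [L/min];  V1 =", x$V1, " V2 =", x$V2, "[L]\n")
  invisible(x)
}

#' Constant-rate oral absorption schedule
#'
#' Oral dosing is modelled as a constant-rate input to the central
#' compartment over an absorption window, so that the administered amount
#' equals the experimental dose. Units: dose in micrograms, times in minutes.
#'
#' @param dose_ug Total administered levodopa amount \[µg\].
#' @param duration_min Absorption period \[min\]; must be positive.
#' @param t_start_min Start of absorption \[min\].
#' @return An object of class `infusion_schedule`.
#' @examples
#' infusion_schedule(dose_ug = 1e5, duration_min = 30)
#' @export
infusion_schedule <- function(dose_ug, duration_min = 30, t_start_min = 0) {
  if (!is.numeric(dose_ug) || dose_ug <= 0) {
    stop("infusion_schedule: `dose_ug` must be positive", call. = FALSE)
  }
  if (!is.numeric(duration_min) || duration_min <= 0) {
    stop("infusion_schedule: `duration_min` must be positive", call. = FALSE)
  }
  if (!is.numeric(t_start_min) || t_start_min < 0) {
    stop("infusion_schedule: `t_start_min` must be non-negative", call. = FALSE)
  }
  structure(list(dose_ug = dose_ug, duration_min = duration_min,
                 t_start_min = t_start_min),
            class = "infusion_schedule")
}

#' Effect-compartment and Hill-law parameters
#'
#' The brain effect compartment is described by the absorption ratio
#' `k31_over_V3` and removal ratio `ke3_over_V3` (both 1/min), a pure
#' transport delay `T` (min), and the Hill law converting delayed
#' effect-compartment concentration into the dimensionless dopaminergic
#' input D: basal level `D0`, maximal drug increment `Dmax`, half-maximum
#' concentration `Dc50` (µg/ml) and Hill coefficient `N`.
#'
#' `k31_over_V3` is a proportionality factor only: rescaling it together
#' with `Dc50` by the same factor leaves D(t) unchanged. The package default
#' 0.01/min puts the effect-compartment gain `k31/ke3` at order unity for
#' the removal rates measured in the levodopa test (0.01-0.035/min), so that
#' half-maximum concentrations on the plasma µg/ml scale are directly usable.
#'
#' @param ke3_over_V3 Effect-compartment removal rate over volume \[1/min\].
#' @param T_delay Pure delay between effect compartment and striatal
#'   action \[min\].
#' @param D0 Basal dopaminergic input (pre-dose), dimensionless in (0, 1).
#' @param Dmax Maximum levodopa-induced increment of D.
#' @param Dc50 Effect-compartment concentration at half-maximum
#'   effect \[µg/ml\].
#' @param N Hill coefficient (>= 1).
#' @param k31_over_V3 Effect-compartment absorption rate over volume
#'   \[1/min\]; fixed across subjects.
#' @return An object of class `effect_params`.
#' @examples
#' effect_params(ke3_over_V3 = 0.02, T_delay = 0, D0 = 0.28,
#'               Dmax = 0.317, Dc50 = 0.03, N = 2)
#' @export
effect_params <- function(ke3_over_V3, T_delay, D0, Dmax, Dc50, N,
                          k31_over_V3 = 0.01) {
  p <- list(ke3_over_V3 = ke3_over_V3, T_delay = T_delay, D0 = D0,
            Dmax = Dmax, Dc50 = Dc50, N = N, k31_over_V3 = k31_over_V3)
  validate_effect_params(p)
  structure(p, class = "effect_params")
}

validate_effect_params <- function(p) {
  need <- c("ke3_over_V3", "T_delay", "D0", "Dmax", "Dc50", "N", "k31_over_V3")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("effect_params: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("effect_params: `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (p$k31_over_V3 <= 0 || p$ke3_over_V3 <= 0) {
    stop("effect_params: rate ratios must be positive", call. = FALSE)
  }
  if (p$T_delay < 0) stop("effect_params: `T_delay` must be >= 0", call. = FALSE)
  # Dmax = 0 (no drug effect) is allowed as a degenerate but valid limit
  if (p$Dmax < 0 || p$Dc50 <= 0) {
    stop("effect_params: `Dmax` must be >= 0 and `Dc50` > 0", call. = FALSE)
  }
  if (p$N < 1) stop("effect_params: Hill coefficient `N` must be >= 1", call. = FALSE)
  if (p$D0 <= 0 || p$D0 + p$Dmax > 1) {
    stop("effect_params: require 0 < D0 and D0 + Dmax <= 1 ",
         "(D is a normalised modulatory input)", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.effect_params <- function(x, ...) {
  cat("<effect_params>  ke3/V3 =", x$ke3_over_V3, " k31/V3 =", x$k31_over_V3,
      "[1/min];  T =", x$T_delay, "min\n  Hill: D0 =", x$D0, " Dmax =", x$Dmax,
      " Dc50 =", x$Dc50, "ug/ml  N =", x$N, "\n")
  invisible(x)
}

#' Basal ganglia network parameters
#'
#' Neuron and modulation constants of the firing-rate basal ganglia model:
#' membrane time constant `tau` (ms) shared by all populations, slow time
#' constant `tau_L` (ms) governing the release of the subthalamic stop
#' signal, logistic activation slope `a` and centre `u0`, Go
#' contrast-enhancement threshold `theta_G`, tonic inputs to GPe/GPi and the
#' cholinergic interneuron (`I_E`, `I_I`, `I_H`), dopamine coefficients on
#' Go/NoGo/cholinergic (`alpha` > 0, `beta` < 0, `gamma` < 0), and noise
#' amplitude `sigma_noise`. `theta_PRE`/`theta_POST` are Hebbian-plasticity
#' thresholds carried for completeness; no plasticity update is executed
#' during a tapping trial.
#'
#' @param tau,tau_L Fast and slow time constants \[ms\].
#' @param a,u0 Logistic activation slope and central point.
#' @param theta_G Go contrast-enhancement threshold on the sensory-related
#'   drive.
#' @param I_E,I_I,I_H Tonic inputs to GPe, GPi and the cholinergic
#'   interneuron.
#' @param alpha,beta,gamma Dopamine coefficients on Go (excitatory), NoGo
#'   (inhibitory) and the cholinergic interneuron (inhibitory).
#' @param sigma_noise Amplitude of Gaussian input noise. The physiological
#'   table value is 0.1; the default here is 0 so that simulations are
#'   deterministic unless noise is explicitly requested (seeded through the
#'   R RNG).
#' @param theta_PRE,theta_POST Hebbian thresholds (carried, unused).
#' @return An object of class `bg_params`.
#' @examples
#' bg_params()
#' bg_params(sigma_noise = 0.1)  # physiological noise level
#' @export
bg_params <- function(tau = 24, tau_L = 120, a = 4, u0 = 1, theta_G = 0.3,
                      I_E = 1, I_I = 3, I_H = 1.25,
                      alpha = 1, beta = -1, gamma = -1, sigma_noise = 0,
                      theta_PRE = 0.5, theta_POST = 0.5) {
  p <- list(tau = tau, tau_L = tau_L, a = a, u0 = u0, theta_G = theta_G,
            I_E = I_E, I_I = I_I, I_H = I_H, alpha = alpha, beta = beta,
            gamma = gamma, sigma_noise = sigma_noise,
            theta_PRE = theta_PRE, theta_POST = theta_POST)
  validate_bg_params(p)
  structure(p, class = "bg_params")
}

validate_bg_params <- function(p) {
  need <- c("tau", "tau_L", "a", "u0", "theta_G", "I_E", "I_I", "I_H",
            "alpha", "beta", "gamma", "sigma_noise", "theta_PRE", "theta_POST")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("bg_params: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("bg_params: `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (p$tau <= 0 || p$tau_L <= 0) stop("bg_params: time constants must be positive", call. = FALSE)
  if (p$a <= 0) stop("bg_params: sigmoid slope `a` must be positive", call. = FALSE)
  if (p$alpha <= 0) stop("bg_params: `alpha` must be positive (dopamine excites Go)", call. = FALSE)
  if (p$beta >= 0) stop("bg_params: `beta` must be negative (dopamine inhibits NoGo)", call. = FALSE)
  if (p$gamma >= 0) stop("bg_params: `gamma` must be negative (dopamine inhibits the cholinergic interneuron)", call. = FALSE)
  if (p$sigma_noise < 0) stop("bg_params: `sigma_noise` must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.bg_params <- function(x, ...) {
  cat("<bg_params>  tau =", x$tau, "ms  tau_L =", x$tau_L, "ms  a =", x$a,
      " u0 =", x$u0, "\n  theta_G =", x$theta_G, " I_E =", x$I_E,
      " I_I =", x$I_I, " I_H =", x$I_H, "\n  alpha =", x$alpha,
      " beta =", x$beta, " gamma =", x$gamma,
      " sigma =", x$sigma_noise, "\n")
  invisible(x)
}

#' Basal ganglia synaptic weights
#'
#' Connection weights of the network, one entry per pathway. Diagonal
#' matrices are stored as their diagonal value (channels are segregated),
#' full matrices as diagonal/off-diagonal pairs. Sign conventions follow the
#' anatomy: inhibitory weights are negative, excitatory positive, and the
#' validator enforces them.
#'
#' @param L Cortical lateral inhibition (extradiagonal), negative.
#' @param W_CS_diag,W_CS_off Cortex <- sensory, diagonal and cross-channel.
#' @param W_CT Cortex <- thalamus (diagonal).
#' @param W_GC Go <- cortex (diagonal).
#' @param W_GS Go <- sensory (diagonal).
#' @param W_NC NoGo <- cortex (diagonal).
#' @param W_NS NoGo <- sensory (diagonal).
#' @param W_EN GPe <- NoGo (diagonal), negative.
#' @param W_IE GPi <- GPe (diagonal), negative.
#' @param W_IG GPi <- Go (diagonal), negative.
#' @param W_TC Thalamus <- cortex (diagonal).
#' @param W_TI Thalamus <- GPi (diagonal), negative.
#' @param w_ESTN GPe <- STN excitation (scalar).
#' @param w_ISTN GPi <- STN excitation (scalar).
#' @param k_E Cortical conflict gain of the hyperdirect pathway (scalar).
#' @param W_STNE STN <- GPe inhibition (per-channel entry), negative.
#' @param w_GH Go <- cholinergic interneuron, negative.
#' @param w_NH NoGo <- cholinergic interneuron, positive.
#' @return An object of class `bg_weights`.
#' @examples
#' bg_weights()
#' @export
bg_weights <- function(L = -1.2, W_CS_diag = 1.1, W_CS_off = 0.2, W_CT = 4,
                       W_GC = 0.48, W_GS = 0.9, W_NC = 1.08, W_NS = 0.1,
                       W_EN = -2.2, W_IE = -3, W_IG = -12, W_TC = 3,
                       W_TI = -3, w_ESTN = 1, w_ISTN = 14, k_E = 7,
                       W_STNE = -1, w_GH = -1, w_NH = 1) {
  w <- list(L = L, W_CS_diag = W_CS_diag, W_CS_off = W_CS_off, W_CT = W_CT,
            W_GC = W_GC, W_GS = W_GS, W_NC = W_NC, W_NS = W_NS, W_EN = W_EN,
            W_IE = W_IE, W_IG = W_IG, W_TC = W_TC, W_TI = W_TI,
            w_ESTN = w_ESTN, w_ISTN = w_ISTN, k_E = k_E, W_STNE = W_STNE,
            w_GH = w_GH, w_NH = w_NH)
  validate_bg_weights(w)
  structure(w, class = "bg_weights")
}

validate_bg_weights <- function(w) {
  need <- c("L", "W_CS_diag", "W_CS_off", "W_CT", "W_GC", "W_GS", "W_NC",
            "W_NS", "W_EN", "W_IE", "W_IG", "W_TC", "W_TI", "w_ESTN",
            "w_ISTN", "k_E", "W_STNE", "w_GH", "w_NH")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("bg_weights: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    v <- w[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("bg_weights: `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  neg <- c("L", "W_EN", "W_IE", "W_IG", "W_TI", "W_STNE", "w_GH")
  pos <- c("W_CS_diag", "W_CT", "W_GC", "W_GS", "W_NC", "W_TC",
           "w_ESTN", "w_ISTN", "k_E", "w_NH")
  for (nm in neg) {
    if (w[[nm]] >= 0) {
      stop("bg_weights: `", nm, "` is an inhibitory connection and must be negative",
           call. = FALSE)
    }
  }
  for (nm in pos) {
    if (w[[nm]] <= 0) {
      stop("bg_weights: `", nm, "` is an excitatory connection and must be positive",
           call. = FALSE)
    }
  }
  if (w$W_CS_off < 0) {
    stop("bg_weights: `W_CS_off` must be >= 0", call. = FALSE)
  }
  invisible(w)
}

#' @export
print.bg_weights <- function(x, ...) {
  cat("<bg_weights> (2 action channels)\n")
  v <- unlist(unclass(x))
  cat(paste0("  ", format(names(v), width = 10), " ", format(v)), sep = "\n")
  invisible(x)
}

#' Levodopa test parameter sets of the six modelled patients
#'
#' Individual pharmacokinetic constants (fitted by Nelder-Mead least squares
#' to plasma concentration) and effect/Hill constants (tuned to the tapping
#' response) for six Parkinson's disease patients: group 1 without motor
#' fluctuations, group 2 with motor fluctuations. `F_val` is the reported
#' final least-squares criterion of the plasma fit. Rate constants are in
#' L/min, `ke3_over_V3` in 1/min, `T_delay` in min, `Dc50` in µg/ml.
#'
#' @return A tibble with one row per patient.
#' @examples
#' ld_patients()
#' @export
ld_patients <- function() {
  tibble::tibble(
    group   = c(1L, 1L, 1L, 2L, 2L, 2L),
    subject = c(1L, 2L, 3L, 1L, 2L, 3L),
    k21     = c(9.11, 8.7, 1.07, 3.53, 1.26, 1.12),
    k12     = c(10.0, 7.4, 1.75, 4.50, 1.77, 1.57),
    ketot   = c(0.80, 1.16, 0.45, 0.65, 0.58, 0.43),
    F_val   = c(0.376, 0.113, 0.448, 0.418, 0.055, 0.235),
    ke3_over_V3 = c(0.01, 0.02, 0.025, 0.03, 0.02, 0.035),
    T_delay = c(15, 0, 0, 15, 15, 0),
    D0      = c(0.29, 0.28, 0.22, 0.27, 0.279, 0.275),
    Dmax    = c(0.50, 0.317, 0.305, 0.304, 0.31, 0.333),
    Dc50    = c(0.25, 0.03, 0.12, 0.13, 0.38, 0.20),
    N       = c(2, 2, 2, 7, 8, 8)
  )
}
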