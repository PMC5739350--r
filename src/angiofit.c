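/* Compiled right-hand side of the coupled VEGF-network / tumor-growth ODE
 * system, called directly by deSolve's integrators (no R-level overhead).
 *
 * State vector: n species concentrations (mol/cm^3 of compartment volume;
 * blood species per cm^3 plasma) followed by the tumor volume V (cm^3).
 *
 * The active model is installed from R via C_set_model() as a list of
 * packed integer/double vectors; the list is preserved so the cached
 * pointers stay valid between calls.  Infusion input (mol/s into plasma)
 * is set per integration segment via C_set_infusion().
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>

typedef struct {
    int n;                      /* number of species (state dim = n + 1) */
    int *comp;                  /* per species: 0 normal, 1 blood, 2 tumor */
    int nr;                     /* reactions */
    int *r1, *r2, *p1, *p2;     /* species indices, -1 = none */
    int *rsc;                   /* 0 linear, 1 fluid-scaled, 2 surface */
    int *rcomp;
    double *rk;
    int ntr;                    /* permeability edges */
    int *tb, *tt, *tcomp;
    double *tperm;              /* cm^3/s per cm^3 tissue */
    int nly;                    /* lymph edges */
    int *lf, *lt;
    double lymph;               /* cm^3/s */
    int nsec;
    int *isec;
    double *qsec;
    int nmt;                    /* maintained densities */
    int *imt, *mmode;           /* mode: 0 constant rho, 1 tumor-cell */
    double *mrho, *mk;
    int nang;
    int *iang;
    double Vn, Vp, phin;        /* normal volume, plasma volume, phi_n */
    double fvasc, fint0, fintmin, lambda, cellvol;
    double k0, k1, psi, Ang0, CAng;
    int variant;                /* 1 or 2 */
    int growth_on;
    int iinf;                   /* plasma drug index, -1 = none */
} model_t;

static model_t M;
static SEXP M_handle = NULL;
static double g_inf_rate = 0.0;
static int model_ready = 0;

static SEXP get_el(SEXP list, const char *name)
{
    SEXP names = getAttrib(list, R_NamesSymbol);
    for (int i = 0; i < length(list); i++)
        if (strcmp(CHAR(STRING_ELT(names, i)), name) == 0)
            return VECTOR_ELT(list, i);
    error("C_set_model: missing element '%s'", name);
    return R_NilValue;
}

static int *iget(SEXP list, const char *name)
{
    SEXP x = get_el(list, name);
    if (TYPEOF(x) != INTSXP) error("element '%s' must be integer", name);
    return INTEGER(x);
}

static double *dget(SEXP list, const char *name)
{
    SEXP x = get_el(list, name);
    if (TYPEOF(x) != REALSXP) error("element '%s' must be double", name);
    return REAL(x);
}

static double dget1(SEXP list, const char *name)
{
    return dget(list, name)[0];
}

static int iget1(SEXP list, const char *name)
{
    return iget(list, name)[0];
}

SEXP C_set_model(SEXP list)
{
    if (M_handle != NULL) {
        R_ReleaseObject(M_handle);
        M_handle = NULL;
    }
    R_PreserveObject(list);
    M_handle = list;

    M.n = iget1(list, "n");
    M.comp = iget(list, "comp");
    M.nr = iget1(list, "nr");
    M.r1 = iget(list, "r1");  M.r2 = iget(list, "r2");
    M.p1 = iget(list, "p1");  M.p2 = iget(list, "p2");
    M.rsc = iget(list, "rsc"); M.rcomp = iget(list, "rcomp");
    M.rk = dget(list, "rk");
    M.ntr = iget1(list, "ntr");
    M.tb = iget(list, "tb"); M.tt = iget(list, "tt");
    M.tcomp = iget(list, "tcomp"); M.tperm = dget(list, "tperm");
    M.nly = iget1(list, "nly");
    M.lf = iget(list, "lf"); M.lt = iget(list, "lt");
    M.lymph = dget1(list, "lymph");
    M.nsec = iget1(list, "nsec");
    M.isec = iget(list, "isec"); M.qsec = dget(list, "qsec");
    M.nmt = iget1(list, "nmt");
    M.imt = iget(list, "imt"); M.mmode = iget(list, "mmode");
    M.mrho = dget(list, "mrho"); M.mk = dget(list, "mk");
    M.nang = iget1(list, "nang");
    M.iang = iget(list, "iang");
    M.Vn = dget1(list, "Vn");   M.Vp = dget1(list, "Vp");
    M.phin = dget1(list, "phin");
    M.fvasc = dget1(list, "fvasc"); M.fint0 = dget1(list, "fint0");
    M.fintmin = dget1(list, "fintmin"); M.lambda = dget1(list, "lambda");
    M.cellvol = dget1(list, "cellvol");
    M.k0 = dget1(list, "k0"); M.k1 = dget1(list, "k1");
    M.psi = dget1(list, "psi"); M.Ang0 = dget1(list, "Ang0");
    M.CAng = dget1(list, "CAng");
    M.variant = iget1(list, "variant");
    M.growth_on = iget1(list, "growth_on");
    M.iinf = iget1(list, "iinf");
    g_inf_rate = 0.0;
    model_ready = 1;
    return R_NilValue;
}

SEXP C_set_infusion(SEXP rate)
{
    g_inf_rate = REAL(rate)[0];
    return R_NilValue;
}

/* deSolve initializer: no scalar parameters are passed this way */
void angiofit_initmod(void (*odeparms)(int *, double *))
{
    int N = 0;
    double dummy = 0.0;
    odeparms(&N, &dummy);
}

static double fint_of_V(double V)
{
    return M.fintmin + (M.fint0 - M.fintmin) * exp(-M.lambda * V);
}

/* core derivative computation; yout[0] = angiogenic signal if wanted */
static void rhs_core(double t, const double *y, double *ydot, double *ang_out)
{
    int n = M.n;
    double V = y[n];
    if (V < 1e-12) V = 1e-12;
    double fint = fint_of_V(V);
    double fcell = 1.0 - fint - M.fvasc;
    double phi[3] = { M.phin, 1.0, fint };
    double vol[3] = { M.Vn, M.Vp, V };

    for (int i = 0; i <= n; i++) ydot[i] = 0.0;

    /* mass-action reactions */
    for (int j = 0; j < M.nr; j++) {
        double a = y[M.r1[j]];
        if (a < 0.0) a = 0.0;
        double rate;
        if (M.r2[j] >= 0) {
            double b = y[M.r2[j]];
            if (b < 0.0) b = 0.0;
            rate = M.rk[j] * a * b;
            if (M.rsc[j] == 1) rate /= phi[M.rcomp[j]];
        } else {
            rate = M.rk[j] * a;
        }
        ydot[M.r1[j]] -= rate;
        if (M.r2[j] >= 0) ydot[M.r2[j]] -= rate;
        if (M.p1[j] >= 0) ydot[M.p1[j]] += rate;
        if (M.p2[j] >= 0) ydot[M.p2[j]] += rate;
    }

    /* transendothelial permeability: moles exchanged via fluid gradients */
    for (int j = 0; j < M.ntr; j++) {
        int c = M.tcomp[j];
        double PS = M.tperm[j] * vol[c];
        double cb = y[M.tb[j]];  if (cb < 0.0) cb = 0.0;
        double ct = y[M.tt[j]];  if (ct < 0.0) ct = 0.0;
        double flux = PS * (cb - ct / phi[c]);   /* mol/s */
        ydot[M.tt[j]] += flux / vol[c];
        ydot[M.tb[j]] -= flux / M.Vp;
    }

    /* lymph: normal interstitium -> blood */
    for (int j = 0; j < M.nly; j++) {
        double cf = y[M.lf[j]];  if (cf < 0.0) cf = 0.0;
        double flux = M.lymph * cf / M.phin;     /* mol/s */
        ydot[M.lf[j]] -= flux / M.Vn;
        ydot[M.lt[j]] += flux / M.Vp;
    }

    /* secretion */
    for (int j = 0; j < M.nsec; j++)
        ydot[M.isec[j]] += M.qsec[j];

    /* angiogenic signal and tumor growth */
    double Ang = 0.0;
    for (int j = 0; j < M.nang; j++) {
        double a = y[M.iang[j]];
        if (a > 0.0) Ang += a;
    }
    double dVdt = 0.0;
    if (M.growth_on) {
        double u = M.psi * log(M.k0 * V / M.k1);
        double lse = (u > 35.0) ? u : log1p(exp(u));
        double simeoni = M.k0 * V * exp(-lse / M.psi);
        double gate;
        if (M.variant == 2)
            gate = 1.0 - (M.Ang0 - M.CAng * Ang) / M.Ang0;
        else
            gate = Ang / M.Ang0;
        if (gate < 0.0) gate = 0.0;
        dVdt = simeoni * gate;
    }

    /* maintained densities: insertion + growth replenishment; dilution of
     * all tumor species by volume expansion */
    double gr = dVdt / V;
    for (int j = 0; j < M.nmt; j++) {
        int i = M.imt[j];
        double target = M.mrho[j];
        if (M.mmode[j] == 1) target *= fcell / M.cellvol;
        ydot[i] += M.mk[j] * target;
        if (M.comp[i] == 2) ydot[i] += gr * target;
    }
    if (M.growth_on && dVdt != 0.0)
        for (int i = 0; i < n; i++)
            if (M.comp[i] == 2) ydot[i] -= gr * y[i];

    /* drug infusion into plasma */
    if (M.iinf >= 0 && g_inf_rate > 0.0)
        ydot[M.iinf] += g_inf_rate / M.Vp;

    ydot[n] = dVdt;
    if (ang_out) *ang_out = Ang;
}

/* deSolve entry point */
void angiofit_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    if (!model_ready) error("no model installed (internal error)");
    if (*neq != M.n + 1)
        error("state dimension %d does not match model (%d species + V)",
              *neq, M.n);
    double ang = 0.0;
    rhs_core(*t, y, ydot, &ang);
    if (ip[0] >= 1) yout[0] = ang;
}

/* single RHS evaluation from R (for tests and diagnostics) */
SEXP C_eval_rhs(SEXP t, SEXP y)
{
    if (!model_ready) error("no model installed");
    int neq = length(y);
    if (neq != M.n + 1)
        error("state length %d does not match model (%d species + V)",
              neq, M.n);
    double *yy = REAL(y);
    for (int i = 0; i < neq; i++)
        if (!R_FINITE(yy[i]))
            error("non-finite value in state at position %d", i + 1);
    SEXP out = PROTECT(allocVector(REALSXP, neq + 1));
    double ang = 0.0;
    rhs_core(REAL(t)[0], yy, REAL(out), &ang);
    REAL(out)[neq] = ang;   /* appended: angiogenic signal */
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_set_model",    (DL_FUNC) &C_set_model,    1},
    {"C_set_infusion", (DL_FUNC) &C_set_infusion, 1},
    {"C_eval_rhs",     (DL_FUNC) &C_eval_rhs,     2},
    {NULL, NULL, 0}
};

void R_init_angiofit(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);  /* deSolve looks up derivs by name */
}
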