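/* Autoxidation reaction-network right-hand side for deSolve's compiled-model
 * interface (lsoda/lsodar).
 *
 * State vector (0-based), fixed three-fatty-acid layout; absent fatty acids
 * simply carry zero concentrations:
 *   fa block f = 0,1,2 ("18:1","18:2","18:3"), base = 10*f:
 *     base+0 LH, +1 L., +2 LOO., +3 LO., +4 LOOH,
 *     base+5 ALD, +6 KET, +7 LOH, +8 EP, +9 EPOOH        [mmol/kg oil]
 *   30 AH, 31 A., 32 Fe2+, 33 Fe3+, 34 O2(oil) [mmol/kg],
 *   35 O2(headspace) [mol], 36 NRP (cumulative lipid units) [mmol/kg]
 *
 * Parameter vector (0-based):
 *   p[18*f + c], c = 0..17 per fatty acid:
 *     0 ki, 1 kp1, 2 kp2, 3 kd, 4 kbimol, 5 kpro1, 6 kpro2,
 *     7 ke1, 8 ke2, 9 ke3, 10 ke4, 11 kald, 12 kket, 13 kloh1, 14 kloh2,
 *     15 kt1, 16 kt2, 17 kt3
 *   54 kAH1, 55 kAH2, 56 kAH3, 57 kt4, 58 kt5
 *   59 alphaALD, 60 alphaLOH, 61 alpha_enabled (0/1)
 *   62 V_HS [m3], 63 V_oil [m3], 64 A_int [m2], 65 oil_mass [kg],
 *   66 k_La [m/s], 67 S_O2 [mmol/kg/atm], 68 P_cap [mol/s/atm],
 *   69 T [K], 70 p_atm_O2 [atm], 71 C_crit [mmol/kg] (root threshold)
 *
 * Units: concentrations mmol/kg oil, time s; second-order constants
 * kg mmol^-1 s^-1, first-order s^-1. Cross-fatty-acid constants are resolved
 * with the hydrogen-donor / radical-species / hydroperoxide-species rules;
 * cross pairs of kbimol and the terminations use the geometric mean.
 */

#include <R.h>
#include <math.h>

#define N_PARMS 72
#define N_STATE 37

static double p[N_PARMS];

void ox_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

#define K(f, c) p[18 * (f) + (c)]
#define RGAS_ATM 8.20573660809596e-5 /* m3 atm / (mol K) */

void ox_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double s[N_STATE], d[N_STATE], dLOOH[3] = {0.0, 0.0, 0.0};
    double o2use = 0.0, r, e, kres;
    int f, g, i;

    /* raw states enter the rate laws: mass action is self-restoring for
     * tiny negative solver undershoots (consumption is linear in the
     * species itself), whereas clamping would make negatives absorbing */
    for (i = 0; i < N_STATE; i++) {
        s[i] = y[i];
        d[i] = 0.0;
    }

    double o2  = s[34];
    double AH  = s[30];
    double Arad = s[31];
    double Fe2 = s[32];
    double Fe3 = s[33];

    for (f = 0; f < 3; f++) {
        int b = 10 * f;
        double LH = s[b], L = s[b + 1], LOO = s[b + 2],
               LO = s[b + 3], LOOH = s[b + 4];

        /* R_i: LH + O2 -> LOO. (initiation straight to peroxyl) */
        r = K(f, 0) * LH * o2;
        d[b] -= r; o2use += r; d[b + 2] += r;

        /* R_p1: L. + O2 -> LOO. */
        r = K(f, 1) * L * o2;
        d[b + 1] -= r; o2use += r; d[b + 2] += r;

        /* R_d: LOOH -> LO. (first order) */
        r = K(f, 3) * LOOH;
        dLOOH[f] -= r; d[b + 3] += r;

        /* R_pro1: LOOH + Fe3+ -> LOO. + Fe2+ */
        r = K(f, 5) * LOOH * Fe3;
        dLOOH[f] -= r; d[33] -= r; d[b + 2] += r; d[32] += r;

        /* R_pro2: LOOH + Fe2+ -> LO. + Fe3+ (Fenton) */
        r = K(f, 6) * LOOH * Fe2;
        dLOOH[f] -= r; d[32] -= r; d[b + 3] += r; d[33] += r;

        /* R_AH1: LOO. + AH -> LOOH + A. */
        r = p[54] * LOO * AH;
        d[b + 2] -= r; d[30] -= r; dLOOH[f] += r; d[31] += r;

        /* R_AH2: LO. + AH -> LOH + A. */
        r = p[55] * LO * AH;
        d[b + 3] -= r; d[30] -= r; d[b + 7] += r; d[31] += r;

        /* R_AH3: L. + AH -> LH + A. */
        r = p[56] * L * AH;
        d[b + 1] -= r; d[30] -= r; d[b] += r; d[31] += r;

        /* R_t4: A. + LOO. -> NRP (one lipid unit) */
        r = p[57] * Arad * LOO;
        d[31] -= r; d[b + 2] -= r; d[36] += r;
    }

    /* second-order lipid-lipid reactions over (radical fa f, partner fa g) */
    for (f = 0; f < 3; f++) {
        int bf = 10 * f;
        double L_f = s[bf + 1], LOO_f = s[bf + 2], LO_f = s[bf + 3];
        for (g = 0; g < 3; g++) {
            int bg = 10 * g;
            double LH_g = s[bg], LOOH_g = s[bg + 4];

            /* R_p2: LOO.(f) + LH(g) -> LOOH(f) + L.(g)   [k of H donor g] */
            r = K(g, 2) * LOO_f * LH_g;
            d[bf + 2] -= r; d[bg] -= r; dLOOH[f] += r; d[bg + 1] += r;

            /* R_ald / R_ket / R_loh1: LO.(f) + LH(g) -> product(f) + L.(g) */
            r = K(g, 11) * LO_f * LH_g;
            d[bf + 3] -= r; d[bg] -= r; d[bf + 5] += r; d[bg + 1] += r;
            r = K(g, 12) * LO_f * LH_g;
            d[bf + 3] -= r; d[bg] -= r; d[bf + 6] += r; d[bg + 1] += r;
            r = K(g, 13) * LO_f * LH_g;
            d[bf + 3] -= r; d[bg] -= r; d[bf + 7] += r; d[bg + 1] += r;

            /* R_loh2: LO.(f) + LOOH(g) -> LOH(f) + LOO.(g)  [k of donor g] */
            r = K(g, 14) * LO_f * LOOH_g;
            d[bf + 3] -= r; dLOOH[g] -= r; d[bf + 7] += r; d[bg + 2] += r;

            /* R_e1: LO.(f) + LH(g) -> EP(f) + L.(g)  [k of radical f] */
            r = K(f, 7) * LO_f * LH_g;
            d[bf + 3] -= r; d[bg] -= r; d[bf + 8] += r; d[bg + 1] += r;

            /* R_e2: LO.(f) + LH(g) -> EPOOH(f) + L.(g)  [k of donor g] */
            r = K(g, 8) * LO_f * LH_g;
            d[bf + 3] -= r; d[bg] -= r; d[bf + 9] += r; d[bg + 1] += r;

            /* R_e3 (PRA): LOO.(f) + LH(g) -> EP(g) + LO.(f)  [k of radical f] */
            r = K(f, 9) * LOO_f * LH_g;
            d[bf + 2] -= r; d[bg] -= r; d[bg + 8] += r; d[bf + 3] += r;

            /* R_e4 (PRA on LOOH): LOO.(f) + LOOH(g) -> EPOOH(g) + LO.(f) */
            r = K(g, 10) * LOO_f * LOOH_g;
            d[bf + 2] -= r; dLOOH[g] -= r; d[bg + 9] += r; d[bf + 3] += r;

            /* R_t2: L.(f) + LOO.(g) -> NRP (two lipid units) */
            kres = sqrt(K(f, 16) * K(g, 16));
            e = kres * L_f * s[bg + 2];
            d[bf + 1] -= e; d[bg + 2] -= e; d[36] += 2.0 * e;
        }
    }

    /* R_bimol: LOOH + LOOH -> LO. + LOO.; the LOOH balance carries the
     * printed term k*[LOOH]^2 once, so the event rate is half that. */
    for (f = 0; f < 3; f++) {
        double LOOH_f = s[10 * f + 4];
        for (g = f; g < 3; g++) {
            if (f == g) {
                e = K(f, 4) * LOOH_f * LOOH_f;
                dLOOH[f] -= e;
                d[10 * f + 3] += 0.5 * e;
                d[10 * f + 2] += 0.5 * e;
            } else {
                kres = sqrt(K(f, 4) * K(g, 4));
                e = kres * LOOH_f * s[10 * g + 4];
                dLOOH[f] -= 0.5 * e; dLOOH[g] -= 0.5 * e;
                d[10 * f + 3] += 0.25 * e; d[10 * g + 3] += 0.25 * e;
                d[10 * f + 2] += 0.25 * e; d[10 * g + 2] += 0.25 * e;
            }
        }
    }

    /* R_t1, R_t3: self- and cross-recombination of L. / LOO. */
    for (f = 0; f < 3; f++) {
        for (g = f; g < 3; g++) {
            if (f == g) {
                e = K(f, 15) * s[10 * f + 1] * s[10 * f + 1];
                d[10 * f + 1] -= 2.0 * e; d[36] += 2.0 * e;
                e = K(f, 17) * s[10 * f + 2] * s[10 * f + 2];
                d[10 * f + 2] -= 2.0 * e; d[36] += 2.0 * e;
            } else {
                kres = sqrt(K(f, 15) * K(g, 15));
                e = kres * s[10 * f + 1] * s[10 * g + 1];
                d[10 * f + 1] -= e; d[10 * g + 1] -= e; d[36] += 2.0 * e;
                kres = sqrt(K(f, 17) * K(g, 17));
                e = kres * s[10 * f + 2] * s[10 * g + 2];
                d[10 * f + 2] -= e; d[10 * g + 2] -= e; d[36] += 2.0 * e;
            }
        }
    }

    /* R_t5: A. + A. -> NRP (no lipid units) */
    e = p[58] * Arad * Arad;
    d[31] -= 2.0 * e;

    /* two-phase oxygen mass transfer */
    {
        double pHS   = s[35] * RGAS_ATM * p[69] / p[62];
        double phi_s = p[66] * p[64] * (p[67] * pHS - o2) * p[65] /
                       p[63] / 1000.0;                 /* mol/s, HS -> oil */
        double phiPe = p[68] * (p[70] - pHS);          /* mol/s, atm -> HS */
        d[35] += phiPe - phi_s;
        d[34] += phi_s * 1000.0 / p[65] - o2use;
    }

    /* assemble LOOH derivatives; NMR-acquisition correction terms (alpha)
     * add alpha * d[LOOH]/dt to ALD and LOH */
    for (f = 0; f < 3; f++) {
        d[10 * f + 4] += dLOOH[f];
        if (p[61] > 0.5) {
            d[10 * f + 5] += p[59] * dLOOH[f];
            d[10 * f + 7] += p[60] * dLOOH[f];
        }
    }

    for (i = 0; i < N_STATE; i++)
        ydot[i] = d[i];
}

/* root: total LOOH crosses the critical acceleration threshold */
void ox_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    gout[0] = (y[4] + y[14] + y[24]) - p[71];
}
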