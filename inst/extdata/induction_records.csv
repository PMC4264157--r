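dog_id,group,induction_index,episode_type,mechanisms,sustained_flag
A1,APO,1,VT,EpFo,TRUE
A1,APO,2,VT,EpFo,TRUE
A1,APO,3,NI,,FALSE
A1,APO,4,NI,,FALSE
A2,APO,1,VF,EFo;RE,TRUE
A2,APO,2,VF,EFo;RE,TRUE
A2,APO,3,VF,EFo;R,TRUE
A2,APO,4,nd,,FALSE
A3,APO,1,VF,EFo;RE,TRUE
A3,APO,2,VT,EFo,TRUE
A3,APO,3,NI,,FALSE
A3,APO,4,nd,,FALSE
A4,APO,1,VT,EFo;R,TRUE
A4,APO,2,VT,EFo;R,TRUE
A4,APO,3,VT_ns,EFo,FALSE
A4,APO,4,NI,,FALSE
A5,APO,1,VT,EFo,TRUE
A5,APO,2,VT,EFo,TRUE
A5,APO,3,VT,EFo,TRUE
A5,APO,4,VF,EFo;RE,TRUE
A6,APO,1,VF,EFo;RE,TRUE
A6,APO,2,VF,EFo;R,TRUE
A6,APO,3,VF,EFo,TRUE
A6,APO,4,VT,EFo;R,TRUE
A7,APO,1,VF,EpFo;R,TRUE
A7,APO,2,VF,EpFo;R,TRUE
A7,APO,3,VF,EFo;R,TRUE
A7,APO,4,VT,EpFo;R,TRUE
A8,APO,1,VT,EFo,TRUE
A8,APO,2,VF,EFo;R,TRUE
A8,APO,3,VT_ns,EFo,FALSE
A8,APO,4,VT_ns,EFo,FALSE
A9,APO,1,VT,EFo;R,TRUE
A9,APO,2,VF,EFo;R,TRUE
A9,APO,3,NI,,FALSE
A9,APO,4,VT_ns,EFo,FALSE
A10,APO,1,VF,EFo,TRUE
A10,APO,2,VF,EFo;RE,TRUE
A10,APO,3,VT,EFo,TRUE
A10,APO,4,NI,,FALSE
O1,OXY,1,VF,EFo;RE,TRUE
O1,OXY,2,VF,EFo;RE,TRUE
O1,OXY,3,VT,EFo,TRUE
O1,OXY,4,VT,EFo,TRUE
O2,OXY,1,VT,R,TRUE
O2,OXY,2,VF,RE,TRUE
O2,OXY,3,VT,RE,TRUE
O2,OXY,4,nd,,FALSE
O3,OXY,1,VT,R,TRUE
O3,OXY,2,VT,R,TRUE
O3,OXY,3,VT,R,TRUE
O3,OXY,4,VT,R,TRUE
O4,OXY,1,VT,EFo;RE,TRUE
O4,OXY,2,VT,EFo;RE,TRUE
O4,OXY,3,NI,,FALSE
O4,OXY,4,NI,,FALSE
O5,OXY,1,VF,RE,TRUE
O5,OXY,2,VF,R,TRUE
O5,OXY,3,VT,R,TRUE
O5,OXY,4,VF,R,TRUE
O6,OXY,1,VF,EFo,TRUE
O6,OXY,2,VT,EFo,TRUE
O6,OXY,3,VF,EFo,TRUE
O6,OXY,4,VF,EFo,TRUE
O7,OXY,1,VF,R,TRUE
O7,OXY,2,VF,R,TRUE
O7,OXY,3,VT,RE,TRUE
O7,OXY,4,VT,EFo;RE,TRUE
O8,OXY,1,VT,EFo,TRUE
O8,OXY,2,VF,EFo;RE,TRUE
O8,OXY,3,VF,R,TRUE
O8,OXY,4,VT_ns,R,FALSE
O9,OXY,1,VF,R,TRUE
O9,OXY,2,VF,RE,TRUE
O9,OXY,3,VF,RE,TRUE
O9,OXY,4,NI,,FALSE
B1,BOTH,1,VT,EpFo;R,TRUE
B1,BOTH,2,VT,EpFo;R,TRUE
B1,BOTH,3,VT,R,TRUE
B1,BOTH,4,VT,R,TRUE
B2,BOTH,1,VT,EFo,TRUE
B2,BOTH,2,VT,EFo,TRUE
B2,BOTH,3,VT_ns,EFo,FALSE
B2,BOTH,4,NI,,FALSE
B3,BOTH,1,VT,R,TRUE
B3,BOTH,2,VT,R,TRUE
B3,BOTH,3,VT,R,TRUE
B3,BOTH,4,nd,,FALSE
B4,BOTH,1,VT,R,TRUE
B4,BOTH,2,VT,R,TRUE
B4,BOTH,3,VT,R,TRUE
B4,BOTH,4,VT,R,TRUE
B5,BOTH,1,VT,EFo,TRUE
B5,BOTH,2,VT,EFo,TRUE
B5,BOTH,3,VT,EFo,TRUE
B5,BOTH,4,nd,,FALSE
B6,BOTH,1,VT,RE,TRUE
B6,BOTH,2,VT,RE,TRUE
B6,BOTH,3,NI,,FALSE
B6,BOTH,4,NI,,FALSE
B7,BOTH,1,VT,EFo,TRUE
B7,BOTH,2,VT,EFo,TRUE
B7,BOTH,3,NI,,FALSE
B7,BOTH,4,NI,,FALSE
B8,BOTH,1,VF,EFo;RE,TRUE
B8,BOTH,2,VF,RE,TRUE
B8,BOTH,3,VF,EFo;RE,TRUE
B8,BOTH,4,NI,,FALSE
C1,CONTROL,1,VT,EpFo,TRUE
C1,CONTROL,2,VT,EpFo,TRUE
C1,CONTROL,3,VT,EFo,TRUE
C1,CONTROL,4,VT,EpFo,TRUE
C2,CONTROL,1,VF,R,TRUE
C2,CONTROL,2,VT,R,TRUE
C2,CONTROL,3,VT,R,TRUE
C2,CONTROL,4,nd,,FALSE
C3,CONTROL,1,VT,R,TRUE
C3,CONTROL,2,VT,R,TRUE
C3,CONTROL,3,VT,R,TRUE
C3,CONTROL,4,VT,R,TRUE
C4,CONTROL,1,VT,R,TRUE
C4,CONTROL,2,VT,R,TRUE
C4,CONTROL,3,VT,R,TRUE
C4,CONTROL,4,VT,R,TRUE
C5,CONTROL,1,VT,R,TRUE
C5,CONTROL,2,VT,R,TRUE
C5,CONTROL,3,VT,R,TRUE
C5,CONTROL,4,VT,R,TRUE
C6,CONTROL,1,VF,EFo;R,TRUE
C6,CONTROL,2,VT,EFo,TRUE
C6,CONTROL,3,VF,EpFo,TRUE
C6,CONTROL,4,VT,EFo,TRUE
C7,CONTROL,1,VF,EFo;R,TRUE
C7,CONTROL,2,VF,EFo;R,TRUE
C7,CONTROL,3,VF,EFo;R,TRUE
C7,CONTROL,4,VF,EFo;R,TRUE
C8,CONTROL,1,VF,EFo;R,TRUE
C8,CONTROL,2,VF,EFo;RE,TRUE
C8,CONTROL,3,VT,EpFo;RE,TRUE
C8,CONTROL,4,VT,EFo;R,TRUE
C9,CONTROL,1,VT,R,TRUE
C9,CONTROL,2,VT,RE,TRUE
C9,CONTROL,3,VF,EFo;RE,TRUE
C9,CONTROL,4,VT,R,TRUE
C10,CONTROL,1,VF,EFo,TRUE
C10,CONTROL,2,VF,EFo;RE,TRUE
C10,CONTROL,3,VF,EFo;RE,TRUE
C10,CONTROL,4,VF,EFo;R,TRUE
C11,CONTROL,1,VF,EFo;RE,TRUE
C11,CONTROL,2,VF,R,TRUE
C11,CONTROL,3,VF,EFo;RE,TRUE
C11,CONTROL,4,VF,EFo;RE,TRUE
C12,CONTROL,1,VT,R,TRUE
C12,CONTROL,2,VF,EpFo;R,TRUE
C12,CONTROL,3,VF,R,TRUE
C12,CONTROL,4,VF,R,TRUE
C13,CONTROL,1,VF,EpFo;R,TRUE
C13,CONTROL,2,VF,RE,TRUE
C13,CONTROL,3,VF,RE,TRUE
C13,CONTROL,4,VF,RE,TRUE
C14,CONTROL,1,VT,RE,TRUE
C14,CONTROL,2,VT,RE,TRUE
C14,CONTROL,3,VT,RE,TRUE
C14,CONTROL,4,VT,RE,TRUE
C15,CONTROL,1,VF,EFo;R,TRUE
C15,CONTROL,2,VF,R,TRUE
C15,CONTROL,3,VF,R,TRUE
C15,CONTROL,4,VF,EFo;R,TRUE
C16,CONTROL,1,VF,R,TRUE
C16,CONTROL,2,VF,EFo;R,TRUE
C16,CONTROL,3,VF,EFo;RE,TRUE
C16,CONTROL,4,VF,R,TRUE
C17,CONTROL,1,VF,RE,TRUE
C17,CONTROL,2,VT,R,TRUE
C17,CONTROL,3,VF,R,TRUE
C17,CONTROL,4,VT,R,TRUE
C18,CONTROL,1,VT,EFo,TRUE
C18,CONTROL,2,VF,EFo;R,TRUE
C18,CONTROL,3,VT,EFo,TRUE
C18,CONTROL,4,VT,EFo,TRUE
C19,CONTROL,1,VF,EFo;RE,TRUE
C19,CONTROL,2,VT,R,TRUE
C19,CONTROL,3,VT,R,TRUE
C19,CONTROL,4,VT,R,TRUE
C20,CONTROL,1,VF,EFo;RE,TRUE
C20,CONTROL,2,VT,EFo;R,TRUE
C20,CONTROL,3,VT,EFo;R,TRUE
C20,CONTROL,4,VT,EFo;R,TRUE
C21,CONTROL,1,VT,R,TRUE
C21,CONTROL,2,VT,R,TRUE
C21,CONTROL,3,VT,R,TRUE
C21,CONTROL,4,VT,R,TRUE
C22,CONTROL,1,VF,RE,TRUE
C22,CONTROL,2,VT,R,TRUE
C22,CONTROL,3,VT,R,TRUE
C22,CONTROL,4,VT,R,TRUE
C23,CONTROL,1,VT,R,TRUE
C23,CONTROL,2,VF,EFo;R,TRUE
C23,CONTROL,3,VF,EFo;R,TRUE
C23,CONTROL,4,VT,EFo,TRUE
C24,CONTROL,1,VT,EFo;R,TRUE
C24,CONTROL,2,VT,EFo;RE,TRUE
C24,CONTROL,3,VF,EFo;R,TRUE
C24,CONTROL,4,VT,EFo;R,TRUE
C25,CONTROL,1,VT,EpFo,TRUE
C25,CONTROL,2,VT,EpFo,TRUE
C25,CONTROL,3,VT,EpFo,TRUE
C25,CONTROL,4,VT,EpFo,TRUE
C26,CONTROL,1,VT,EFo;R,TRUE
C26,CONTROL,2,VT,EFo,TRUE
C26,CONTROL,3,VT,EFo,TRUE
C26,CONTROL,4,VT,EFo,TRUE
C27,CONTROL,1,VF,EFo,TRUE
C27,CONTROL,2,VT,EFo,TRUE
C27,CONTROL,3,VT,EFo;R,TRUE
C27,CONTROL,4,VT,EpFo,TRUE
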